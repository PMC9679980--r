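# Synthetic labeled protein sets with a planted, recoverable thermal
# signal, plus fake secondary-structure and domain annotations, so the
# whole pipeline is testable without external data.

#' Specification of a synthetic labeled sequence set
#'
#' Describes how sequences and labels are generated: residues are drawn
#' i.i.d. from `backgroundFreqs`, motif occurrences are planted at random
#' non-overlapping positions (a per-sequence occurrence count drawn
#' uniformly from `0:maxOccurrences`), and the label is
#' `base + sum(beta * motif count) + sum(compositionEffects * letter
#' frequency) + N(0, noiseSd)` degrees Celsius. The defaults emulate a
#' mesophile-like set: lengths 100-120 (so flanked occlusion fits a
#' 128-residue model input), uniform residue background, a single planted
#' 5-mer motif worth +2.5 degrees per occurrence, intercept 30 and noise
#' sd 2 - a signal a small network can recover while labels stay strictly
#' positive (the relevance score divides by the unoccluded prediction).
#'
#' @param n Number of records.
#' @param lengthRange Integer (min, max) sequence length in residues.
#' @param backgroundFreqs 20 background residue probabilities (sum 1),
#'   ordered as [aminoAlphabet()].
#' @param motifs List of `list(motif =, beta =)` entries: motif string and
#'   its label effect in degrees Celsius per occurrence.
#' @param maxOccurrences Maximum planted occurrences per motif (count
#'   drawn uniformly from 0..`maxOccurrences`).
#' @param compositionEffects Optional named coefficients (degrees per unit
#'   letter frequency).
#' @param base Label intercept (degrees Celsius, positive).
#' @param noiseSd Label noise standard deviation (degrees Celsius).
#' @param labelDistribution Optional `list(min =, max =, binWidth =,
#'   weights =)`: when set, labels are drawn stratified from the given
#'   histogram (uniform within bins; `weights` default to uniform across
#'   bins) instead of from the planted function - an imbalance-emulation
#'   mode for testing rebalancing.
#' @param motifSsCode DSSP code forced at motif positions in the fake
#'   secondary-structure strings (default "G"), giving enrichment analyses
#'   a planted truth.
#' @param seed Integer seed.
#' @return A list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(n = 500L,
                          lengthRange = c(100L, 120L),
                          backgroundFreqs = rep(1 / 20, 20),
                          motifs = list(list(motif = "WYMHK", beta = 2.5)),
                          maxOccurrences = 4L,
                          compositionEffects = NULL,
                          base = 30,
                          noiseSd = 2,
                          labelDistribution = NULL,
                          motifSsCode = "G",
                          seed = 1L) {
  stopifnot(n >= 1, length(lengthRange) == 2L,
            lengthRange[1] <= lengthRange[2],
            length(backgroundFreqs) == 20L,
            abs(sum(backgroundFreqs) - 1) < 1e-8,
            noiseSd >= 0, base > 0, motifSsCode %in% .DSSP8)
  for (m in motifs) {
    if (nchar(m$motif) > lengthRange[1])
      stop(sprintf("motif '%s' is longer than the minimum sequence length",
                   m$motif), call. = FALSE)
    if (grepl(sprintf("[^%s]", paste(.AA20, collapse = "")), m$motif))
      stop("motifs must use the standard 20-letter alphabet", call. = FALSE)
  }
  structure(list(n = as.integer(n), lengthRange = as.integer(lengthRange),
                 backgroundFreqs = backgroundFreqs, motifs = motifs,
                 maxOccurrences = as.integer(maxOccurrences),
                 compositionEffects = compositionEffects,
                 base = base, noiseSd = noiseSd,
                 labelDistribution = labelDistribution,
                 motifSsCode = motifSsCode, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# Count (possibly overlapping) motif occurrences in each sequence.
.motifCounts <- function(motif, seqs) {
  pat <- sprintf("(?=%s)", motif)
  vapply(seqs, function(s) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' Noiseless planted labels recomputed from sequences
#'
#' Evaluates the deterministic part of the label model on the actual
#' sequences (motif occurrences counted with overlaps): with `noiseSd = 0`
#' the generated labels equal these values exactly.
#'
#' @param spec A [syntheticSpec()].
#' @param x A [ProteinSet-class] or character vector of sequences.
#' @return Numeric vector of labels in degrees Celsius.
#' @export
syntheticLabels <- function(spec, x) {
  seqs <- if (is(x, "ProteinSet")) .seqStrings(x) else toupper(as.character(x))
  lab <- rep(spec$base, length(seqs))
  for (m in spec$motifs)
    lab <- lab + m$beta * .motifCounts(m$motif, seqs)
  if (!is.null(spec$compositionEffects)) {
    for (aa in names(spec$compositionEffects)) {
      f <- vapply(seqs, function(s)
        lengths(regmatches(s, gregexpr(aa, s, fixed = TRUE))) / nchar(s),
        numeric(1), USE.NAMES = FALSE)
      lab <- lab + spec$compositionEffects[[aa]] * f
    }
  }
  lab
}

.sampleRunLengthSS <- function(L, codes = .DSSP8) {
  out <- character(0)
  while (length(out) < L) {
    code <- sample(codes, 1L)
    out <- c(out, rep(code, sample(3:12, 1L)))
  }
  paste(out[seq_len(L)], collapse = "")
}

# Place `count` non-overlapping occurrences of a motif; returns start
# positions (may place fewer if space runs out, which cannot happen at the
# default sizes).
.placeMotifs <- function(L, mLen, count, occupied) {
  starts <- integer(0)
  avail <- seq_len(L - mLen + 1L)
  for (j in seq_len(count)) {
    ok <- avail[vapply(avail, function(s)
      !any(occupied[s:(s + mLen - 1L)]), logical(1))]
    if (length(ok) == 0L) break
    s <- if (length(ok) == 1L) ok else sample(ok, 1L)
    starts <- c(starts, s)
    occupied[s:(s + mLen - 1L)] <- TRUE
  }
  list(starts = starts, occupied = occupied)
}

#' Generate a synthetic labeled protein set
#'
#' Draws sequences, plants motifs, computes labels, and fabricates
#' annotations: per motif occurrence one eligible domain interval (length
#' at most half the protein) containing the occurrence, and a run-length
#' sampled secondary-structure string with motif positions forced to the
#' designated code. Fully reproducible under the spec seed.
#'
#' @param spec A [syntheticSpec()].
#' @return A list of class `SyntheticData`: `set` (a labeled
#'   [ProteinSet-class] with ss and domain annotations), `truth` (a list
#'   with `motifs` - `data.frame(id, motif, start, end)` - and `motifMask`,
#'   per-record strings marking planted positions with `M`), and `spec`.
#' @examples
#' sd <- generateSynthetic(syntheticSpec(n = 5, seed = 42))
#' sd$set
#' @export
generateSynthetic <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  .withSeed(spec$seed, {
    n <- spec$n
    ids <- sprintf("SYN%05d", seq_len(n))
    seqs <- character(n)
    ssv <- character(n)
    doms <- vector("list", n)
    masks <- character(n)
    motifRows <- list()
    for (i in seq_len(n)) {
      L <- sample(spec$lengthRange[1]:spec$lengthRange[2], 1L)
      chars <- sample(.AA20, L, replace = TRUE, prob = spec$backgroundFreqs)
      occupied <- rep(FALSE, L)
      drows <- list()
      for (m in spec$motifs) {
        mLen <- nchar(m$motif)
        count <- sample(0:spec$maxOccurrences, 1L)
        pl <- .placeMotifs(L, mLen, count, occupied)
        occupied <- pl$occupied
        for (s in pl$starts) {
          chars[s:(s + mLen - 1L)] <- strsplit(m$motif, "")[[1]]
          # one eligible domain per occurrence, containing it
          dMax <- floor(L / 2)
          ext <- max(0L, sample(0:max(0L, dMax - mLen), 1L))
          left <- sample(0:ext, 1L)
          ds <- max(1L, s - left)
          de <- min(L, s + mLen - 1L + (ext - left))
          drows[[length(drows) + 1L]] <- data.frame(
            name = sprintf("%s_dom%d", ids[i], length(drows) + 1L),
            start = ds, end = de, stringsAsFactors = FALSE)
          motifRows[[length(motifRows) + 1L]] <- data.frame(
            id = ids[i], motif = m$motif, start = s, end = s + mLen - 1L,
            stringsAsFactors = FALSE)
        }
      }
      seqs[i] <- paste(chars, collapse = "")
      ss <- strsplit(.sampleRunLengthSS(L), "")[[1]]
      ss[occupied] <- spec$motifSsCode
      ssv[i] <- paste(ss, collapse = "")
      doms[i] <- list(if (length(drows)) do.call(rbind, drows) else NULL)
      masks[i] <- paste(ifelse(occupied, "M", "."), collapse = "")
    }
    if (!is.null(spec$labelDistribution)) {
      ld <- spec$labelDistribution
      bw <- if (is.null(ld$binWidth)) 5 else ld$binWidth
      edges <- seq(ld$min, ld$max, by = bw)
      nb <- length(edges) - 1L
      wts <- if (is.null(ld$weights)) rep(1 / nb, nb) else ld$weights / sum(ld$weights)
      counts <- floor(n * wts)
      rem <- n - sum(counts)
      if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
      lab <- unlist(lapply(seq_len(nb), function(b)
        stats::runif(counts[b], edges[b], edges[b + 1L])))
      lab <- sample(lab)
    } else {
      lab <- syntheticLabels(spec, seqs) +
        stats::rnorm(n, 0, spec$noiseSd)
    }
    set <- proteinSet(seqs, ids = ids, label = lab, ss = ssv,
                      domains = doms, setName = "synthetic")
    truth <- list(
      motifs = if (length(motifRows)) do.call(rbind, motifRows)
               else data.frame(id = character(0), motif = character(0),
                               start = integer(0), end = integer(0)),
      motifMask = stats::setNames(masks, ids))
    structure(list(set = set, truth = truth, spec = spec),
              class = "SyntheticData")
  })
}

#' @export
print.SyntheticData <- function(x, ...) {
  cat(sprintf("SyntheticData: %d records, %d planted motif occurrences\n",
              length(x$set), nrow(x$truth$motifs)))
  invisible(x)
}

#' Generate a bimodal (imbalanced) labeled set
#'
#' Emulates the mesophile-heavy label imbalance of real corpora: sequences
#' are generated as in [generateSynthetic()] but labels are drawn from a
#' two-component normal mixture (defaults: 90% at 30 degrees, 10% at 70,
#' sd 1.5). Feeding the result to [uniformSubsample()] must flatten the
#' histogram.
#'
#' @param spec A [syntheticSpec()]; its planted label function is ignored.
#' @param weights,means,sds Mixture weights, component means and sds.
#' @return A labeled [ProteinSet-class].
#' @export
emulateImbalance <- function(spec, weights = c(0.9, 0.1),
                             means = c(30, 70), sds = c(1.5, 1.5)) {
  stopifnot(inherits(spec, "SyntheticSpec"),
            length(weights) == length(means),
            length(means) == length(sds),
            all(weights > 0))
  sim <- generateSynthetic(spec)
  set <- sim$set
  lab <- .withSeed(spec$seed + 1L, {
    comp <- sample(seq_along(weights), length(set), replace = TRUE,
                   prob = weights / sum(weights))
    stats::rnorm(length(set), means[comp], sds[comp])
  })
  labels(set) <- lab
  setName(set) <- "synthetic.imbalanced"
  set
}

#' Write a synthetic data set to disk
#'
#' Writes FASTA, a label TSV, secondary-structure and domain TSVs, and a
#' ground-truth JSON (planted motif coordinates) into a directory.
#'
#' @param sim A `SyntheticData` from [generateSynthetic()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (named character vector).
#' @export
writeSyntheticData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set <- sim$set
  paths <- c(
    fasta = file.path(dir, "sequences.fasta"),
    labels = file.path(dir, "labels.tsv"),
    ss = file.path(dir, "ss.tsv"),
    domains = file.path(dir, "domains.tsv"),
    truth = file.path(dir, "truth.json"))
  writeFastaSet(set, paths["fasta"])
  writeLabelsTsv(data.frame(id = names(set), label = labels(set)),
                 paths["labels"])
  utils::write.table(data.frame(id = names(set), ss = ssAnnotation(set)),
                     paths["ss"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  dl <- domainAnnotation(set)
  drows <- do.call(rbind, lapply(seq_along(dl), function(i) {
    if (is.null(dl[[i]])) return(NULL)
    cbind(id = names(set)[i], dl[[i]])
  }))
  if (is.null(drows))
    drows <- data.frame(id = character(0), name = character(0),
                        start = integer(0), end = integer(0))
  utils::write.table(drows, paths["domains"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(motifs = sim$truth$motifs,
                            motifMask = as.list(sim$truth$motifMask)),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
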