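# Occlusion-based interpretation: per-residue relevance profiles,
# significance calling, category enrichment and domain-coverage statistics.

#' Build a relevance profile from raw per-residue scores
#'
#' Standardizes scores within the profile (z has mean 0 and unit variance
#' whenever the score standard deviation is positive; an all-constant score
#' vector yields z = 0 everywhere) and calls positions significant when
#' `|z| > zThreshold` (strict inequality).
#'
#' @param id Record identifier.
#' @param scores Numeric per-residue scores.
#' @param width Occlusion window length the scores came from (bookkeeping).
#' @param zThreshold Significance threshold on `|z|` (default 2).
#' @return A [RelevanceProfile-class].
#' @examples
#' p <- relevanceProfileFromScores("P1", rnorm(100), width = 5)
#' mean(p@z)
#' @export
relevanceProfileFromScores <- function(id, scores, width = 5L, zThreshold = 2) {
  s <- stats::sd(scores)
  z <- if (is.na(s) || s == 0) rep(0, length(scores))
       else (scores - mean(scores)) / s
  new("RelevanceProfile", id = as.character(id), scores = as.numeric(scores),
      z = z, significant = abs(z) > zThreshold, width = as.integer(width),
      zThreshold = zThreshold)
}

setMethod("show", "RelevanceProfile", function(object) {
  cat(sprintf(
    "RelevanceProfile '%s': %d positions, width %d, %d significant (|z| > %g)\n",
    object@id, length(object@scores), object@width,
    sum(object@significant), object@zThreshold))
})

#' Occlusion relevance profile of one protein
#'
#' Slides an occlusion window of `width` residues along the sequence (stride
#' 1) and measures the relative change in the model's prediction when the
#' window's one-hot columns are zeroed:
#' `(prediction_occluded - prediction_wt) / prediction_wt`. So that every
#' original position is covered by a full complement of `width` windows, the
#' sequence is first flanked at each end by `width - 1` repeats of its
#' terminal residue. A residue's raw score is the mean of the scores of all
#' windows covering it (a moving average over the window scores); the
#' profile is then standardized within the protein and trimmed to the
#' original sequence length.
#'
#' @param model A [ThermoNet-class].
#' @param record A [ProteinSet-class] of length 1, or a single sequence
#'   string (optionally named).
#' @param width Occlusion window length (default 5 residues); must be
#'   smaller than the sequence length, and the flanked sequence
#'   (`length + 2*(width-1)`) must fit the model input length.
#' @param zThreshold Significance threshold on `|z|` (default 2).
#' @return A [RelevanceProfile-class] of the same length as the sequence.
#' @export
occlusionProfile <- function(model, record, width = 5L, zThreshold = 2) {
  if (is(record, "ProteinSet")) {
    stopifnot(length(record) == 1L)
    s <- .seqStrings(record)
    id <- names(record)
  } else {
    s <- toupper(as.character(record))
    id <- if (!is.null(names(record))) names(record) else "seq1"
  }
  L <- nchar(s)
  width <- as.integer(width)
  if (width < 1L) stop("width must be >= 1", call. = FALSE)
  if (width >= L)
    stop(sprintf("occlusion width %d must be smaller than sequence length %d",
                 width, L), call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  flanked <- paste0(strrep(chars[1L], width - 1L), s,
                    strrep(chars[L], width - 1L))
  Lf <- nchar(flanked)
  Lmax <- model@config@inputLength
  if (Lf > Lmax)
    stop(sprintf("flanked sequence length %d exceeds model input length %d",
                 Lf, Lmax), call. = FALSE)
  base <- oneHot(flanked, Lmax)$matrix
  predWt <- as.numeric(predict(model, flanked))
  if (predWt == 0)
    stop("unoccluded prediction is 0; relative relevance undefined",
         call. = FALSE)
  nw <- Lf - width + 1L
  X <- matrix(0, nw * Lmax, 20L)
  for (t in seq_len(nw)) {
    m <- base
    m[t:(t + width - 1L), ] <- 0
    X[((t - 1L) * Lmax + 1L):(t * Lmax), ] <- m
  }
  preds <- .forwardInference(model, X, nw)$pred
  winScore <- (preds - predWt) / predWt
  # original position i sits at flanked position i + width - 1 and is
  # covered by windows i .. i + width - 1
  raw <- vapply(seq_len(L), function(i) mean(winScore[i:(i + width - 1L)]),
                numeric(1))
  relevanceProfileFromScores(id, raw, width = width, zThreshold = zThreshold)
}

#' Overlap of significant positions across occlusion widths
#'
#' Recomputes the relevance profile at several occlusion widths and returns
#' the Jaccard overlap of the significant-position sets for every width
#' pair. The Jaccard index of two empty sets is defined as 1 (two widths
#' that both flag nothing are in perfect agreement).
#'
#' @param model A [ThermoNet-class].
#' @param record As in [occlusionProfile()].
#' @param widths Integer vector of occlusion widths (default 2, 5, 10, 20).
#' @return A symmetric matrix of Jaccard overlaps with widths as dimnames.
#' @export
stabilityCheck <- function(model, record, widths = c(2L, 5L, 10L, 20L)) {
  sets <- lapply(widths, function(w)
    which(occlusionProfile(model, record, width = w)@significant))
  k <- length(widths)
  out <- matrix(1, k, k, dimnames = list(widths, widths))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    a <- sets[[i]]
    b <- sets[[j]]
    u <- length(union(a, b))
    out[i, j] <- if (u == 0L) 1 else length(intersect(a, b)) / u
  }
  out
}

#' Category enrichment at significant profile positions
#'
#' Pools positions across relevance profiles and tests each category
#' (amino-acid letter, DSSP code, or any per-position annotation) for over-
#' and under-representation among significant positions versus the
#' background, with one-sided hypergeometric tests in both directions.
#' Positions whose annotation character is not in `alphabet` count as
#' unannotated and are excluded from the background, the significant set and
#' all counts.
#'
#' @param profiles A list of [RelevanceProfile-class] objects.
#' @param annotations Named character vector (or list) of per-record
#'   annotation strings, indexed by profile id; each string must match the
#'   profile length. For amino-acid enrichment pass the sequences
#'   themselves.
#' @param alphabet Character vector of category symbols to test.
#' @param alpha Significance threshold on the smaller tail p-value
#'   (default 0.05, uncorrected as is conventional for this analysis;
#'   apply [stats::p.adjust] to the returned columns for a corrected view).
#' @return A `data.frame` with one row per category: counts `k` (category
#'   at significant positions), `n_sig`, `K` (background category count),
#'   `N` (background total), the upper-tail `p_over`, lower-tail `p_under`,
#'   and a `verdict` of `enriched`, `depleted` or `neither`.
#' @export
enrichCategories <- function(profiles, annotations, alphabet, alpha = 0.05) {
  if (is(profiles, "RelevanceProfile")) profiles <- list(profiles)
  allCat <- character(0)
  allSig <- logical(0)
  for (p in profiles) {
    ann <- annotations[[p@id]]
    if (is.null(ann) || is.na(ann)) next
    cats <- strsplit(as.character(ann), "")[[1]]
    if (length(cats) != length(p@significant))
      stop(sprintf("annotation length (%d) does not match profile '%s' (%d)",
                   length(cats), p@id, length(p@significant)), call. = FALSE)
    keep <- cats %in% alphabet
    allCat <- c(allCat, cats[keep])
    allSig <- c(allSig, p@significant[keep])
  }
  N <- length(allCat)
  nSig <- sum(allSig)
  res <- lapply(alphabet, function(cc) {
    K <- sum(allCat == cc)
    k <- sum(allCat == cc & allSig)
    pOver <- stats::phyper(k - 1, K, N - K, nSig, lower.tail = FALSE)
    pUnder <- stats::phyper(k, K, N - K, nSig, lower.tail = TRUE)
    verdict <- if (pOver < alpha && pOver <= pUnder) "enriched"
               else if (pUnder < alpha && pUnder < pOver) "depleted"
               else "neither"
    data.frame(category = cc, k = k, n_sig = nSig, K = K, N = N,
               p_over = pOver, p_under = pUnder, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Coverage of annotated domains by significant positions
#'
#' For each domain no longer than half the protein (the eligibility rule
#' that keeps the control balanced), computes the fraction of domain
#' positions that are significant, plus a control: the sequence outside the
#' domain is kept as contiguous segments, every possible window of the
#' domain's length within those segments is counted, and the expected
#' significant count per window (significant positions outside / number of
#' windows) is divided by the domain length. Ineligible domains are flagged
#' and not scored; if the outside segments admit no full-length window the
#' control is reported as missing.
#'
#' @param profile A [RelevanceProfile-class].
#' @param domains A `data.frame` with columns `name`, `start`, `end`
#'   (1-based inclusive, within the sequence).
#' @return A `data.frame(name, start, end, length, eligible, coverage,
#'   control)`.
#' @export
domainCoverage <- function(profile, domains) {
  L <- length(profile@significant)
  sig <- profile@significant
  if (nrow(domains) == 0L)
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      eligible = logical(0), coverage = numeric(0),
                      control = numeric(0), stringsAsFactors = FALSE))
  if (any(domains$start < 1L) || any(domains$end > L) ||
      any(domains$start > domains$end))
    stop("domain intervals must lie within the sequence", call. = FALSE)
  res <- lapply(seq_len(nrow(domains)), function(i) {
    s <- domains$start[i]
    e <- domains$end[i]
    d <- e - s + 1L
    eligible <- d <= L / 2
    coverage <- NA_real_
    control <- NA_real_
    if (eligible) {
      coverage <- sum(sig[s:e]) / d
      segLens <- c(s - 1L, L - e)
      nWin <- sum(pmax(0L, segLens - d + 1L))
      sigOut <- sum(sig[-(s:e)])
      if (nWin > 0L) control <- (sigOut / nWin) / d
    }
    data.frame(name = domains$name[i], start = s, end = e, length = d,
               eligible = eligible, coverage = coverage, control = control,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Select domains by significant-position coverage
#'
#' Returns the names of eligible domains whose coverage meets the cutoff,
#' sorted by coverage (descending), ties broken by name.
#'
#' @param coverages A `data.frame` as returned by [domainCoverage()]
#'   (possibly row-bound over proteins).
#' @param cutoff Minimum coverage fraction (default 0.30).
#' @return Character vector of domain names.
#' @export
selectDomains <- function(coverages, cutoff = 0.30) {
  if (nrow(coverages) == 0L) return(character(0))
  sel <- coverages[coverages$eligible & !is.na(coverages$coverage) &
                     coverages$coverage >= cutoff, , drop = FALSE]
  sel <- sel[order(-sel$coverage, sel$name), , drop = FALSE]
  sel$name
}

#' Write relevance profiles as TSV
#'
#' One row per residue: id, position (1-based), residue, score, z,
#' significant.
#'
#' @param profiles List of [RelevanceProfile-class] objects.
#' @param x The [ProteinSet-class] the profiles came from (for residues).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProfilesTsv <- function(profiles, x, path) {
  if (is(profiles, "RelevanceProfile")) profiles <- list(profiles)
  seqs <- stats::setNames(.seqStrings(x), names(x))
  rows <- lapply(profiles, function(p) {
    res <- strsplit(seqs[[p@id]], "")[[1]]
    data.frame(id = p@id, position = seq_along(p@scores), residue = res,
               score = p@scores, z = p@z, significant = p@significant,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
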