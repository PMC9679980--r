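#' Construct a ProteinSet
#'
#' Builds the package's central sequence container from character sequences
#' (or an `AAStringSet`) plus optional labels and annotations.
#'
#' @param sequences Character vector of amino-acid sequences, or an
#'   `AAStringSet`. Lowercase input is uppercased.
#' @param ids Character vector of identifiers; defaults to existing names.
#' @param label Optional numeric temperature labels in degrees Celsius
#'   (`NA` where absent).
#' @param ss Optional character vector of per-residue secondary-structure
#'   strings over the DSSP 8-letter codes (`NA` where absent).
#' @param domains Optional list of per-record domain tables (`NULL` or a
#'   `data.frame` with columns `name`, `start`, `end`; 1-based inclusive).
#' @param setName Name of the set.
#'
#' @return A [ProteinSet-class] object.
#' @examples
#' ps <- proteinSet(c(P1 = "ACDEFGHIKL", P2 = "MNPQRSTVWY"), label = c(37, 55))
#' labels(ps)
#' @export
proteinSet <- function(sequences, ids = NULL, label = NULL, ss = NULL,
                       domains = NULL, setName = "proteins") {
  if (is.null(ids)) ids <- names(sequences)
  seqs <- toupper(as.character(sequences))
  n <- length(seqs)
  if (is.null(ids))
    ids <- if (n == 0L) character(0) else paste0("seq", seq_len(n))
  aas <- Biostrings::AAStringSet(seqs)
  names(aas) <- as.character(ids)
  if (is.null(label)) label <- rep(NA_real_, n)
  if (is.null(ss)) ss <- rep(NA_character_, n)
  if (is.null(domains)) domains <- vector("list", n)
  new("ProteinSet", sequences = aas, label = as.numeric(label),
      ss = as.character(ss), domains = domains, setName = setName)
}

#' Accessors for ProteinSet
#'
#' `sequences()` returns the underlying `AAStringSet`; `labels()` the numeric
#' temperature labels; `ssAnnotation()` the secondary-structure strings;
#' `domainAnnotation()` the per-record domain tables; `setName()` the set
#' name. Replacement forms are provided for labels and annotations.
#'
#' @param x,object A [ProteinSet-class] object.
#' @param value Replacement value.
#' @param ... Unused.
#' @return The respective component.
#' @name ProteinSet-accessors
NULL

#' @rdname ProteinSet-accessors
#' @export
setMethod("sequences", "ProteinSet", function(x) x@sequences)

#' @rdname ProteinSet-accessors
#' @export
setMethod("labels", "ProteinSet", function(object, ...) object@label)

#' @rdname ProteinSet-accessors
#' @export
setReplaceMethod("labels", "ProteinSet", function(x, value) {
  x@label <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname ProteinSet-accessors
#' @export
setMethod("ssAnnotation", "ProteinSet", function(x) x@ss)

#' @rdname ProteinSet-accessors
#' @export
setReplaceMethod("ssAnnotation", "ProteinSet", function(x, value) {
  x@ss <- as.character(value)
  validObject(x)
  x
})

#' @rdname ProteinSet-accessors
#' @export
setMethod("domainAnnotation", "ProteinSet", function(x) x@domains)

#' @rdname ProteinSet-accessors
#' @export
setReplaceMethod("domainAnnotation", "ProteinSet", function(x, value) {
  x@domains <- value
  validObject(x)
  x
})

#' @rdname ProteinSet-accessors
#' @export
setMethod("setName", "ProteinSet", function(x) x@setName)

#' @rdname ProteinSet-accessors
#' @export
setReplaceMethod("setName", "ProteinSet", function(x, value) {
  x@setName <- as.character(value)
  validObject(x)
  x
})

#' @rdname ProteinSet-accessors
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' @rdname ProteinSet-accessors
#' @export
setMethod("names", "ProteinSet", function(x) names(x@sequences))

#' @param i Index (integer, logical or id character vector).
#' @param j,drop Unused.
#' @rdname ProteinSet-accessors
#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  initialize(x,
    sequences = x@sequences[i],
    label = x@label[i],
    ss = x@ss[i],
    domains = x@domains[i],
    setName = x@setName)
})

setMethod("show", "ProteinSet", function(object) {
  n <- length(object)
  w <- if (n) Biostrings::width(object@sequences) else integer()
  cat(sprintf("ProteinSet '%s' with %d sequence%s\n", object@setName, n,
              if (n == 1) "" else "s"))
  if (n) {
    cat(sprintf("  lengths: %d-%d; labeled: %d; ss: %d; with domains: %d\n",
                min(w), max(w), sum(!is.na(object@label)),
                sum(!is.na(object@ss)),
                sum(!vapply(object@domains, is.null, logical(1)))))
  }
})

#' Read protein sequences from a FASTA file
#'
#' Reads a FASTA file into a [ProteinSet-class]. The header token before the
#' first whitespace becomes the record id and sequences are uppercased. An
#' empty file yields an empty set. A sequence line appearing before any
#' header is a parse error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @param setName Name for the resulting set.
#' @return A [ProteinSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 desc", "ACDEF", ">P2", "ghikl"), fa)
#' readFastaSet(fa)
#' @export
readFastaSet <- function(path, setName = basename(path)) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), ";"))
  if (length(nonblank) == 0L)
    return(proteinSet(character(0), setName = setName))
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA: sequence data before any header at line %d", first),
         call. = FALSE)
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "[ \t]"), `[`, character(1), 1L)
  proteinSet(as.character(aas), ids = ids, setName = setName)
}

#' Write a ProteinSet to FASTA
#'
#' @param x A [ProteinSet-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeFastaSet <- function(x, path) {
  Biostrings::writeXStringSet(x@sequences, filepath = path)
  invisible(path)
}

#' Read / write tab-separated label and annotation tables
#'
#' Plain two-column TSV readers matching the package's external formats:
#' labels are `id <TAB> temperature`, secondary structure is
#' `id <TAB> ss_string`, and domains are
#' `id <TAB> name <TAB> start <TAB> end` (1-based inclusive). No header row.
#'
#' @param path File path.
#' @return `readLabelsTsv`: `data.frame(id, label)`; `readSsTsv`:
#'   `data.frame(id, ss)`; `readDomainsTsv`:
#'   `data.frame(id, name, start, end)`.
#' @name label-io
NULL

#' @rdname label-io
#' @export
readLabelsTsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label TSV must have two columns (id, label)", call. = FALSE)
  lab <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(lab) && !all(is.na(df[[2L]])))
    stop("non-numeric label in ", path, call. = FALSE)
  data.frame(id = as.character(df[[1L]]), label = lab, stringsAsFactors = FALSE)
}

#' @rdname label-io
#' @param df Data frame to write.
#' @export
writeLabelsTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname label-io
#' @export
readSsTsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(id = as.character(df[[1L]]), ss = as.character(df[[2L]]),
             stringsAsFactors = FALSE)
}

#' @rdname label-io
#' @export
readDomainsTsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stop("domain TSV must have four columns (id, name, start, end)", call. = FALSE)
  data.frame(id = as.character(df[[1L]]), name = as.character(df[[2L]]),
             start = as.integer(df[[3L]]), end = as.integer(df[[4L]]),
             stringsAsFactors = FALSE)
}

#' Assemble a ProteinSet from FASTA plus annotation tables
#'
#' Convenience loader joining a FASTA file with optional label,
#' secondary-structure and domain TSV tables by record id.
#'
#' @param fasta FASTA path.
#' @param labels,ss,domains Optional TSV paths (see [readLabelsTsv]).
#' @param setName Set name.
#' @return A [ProteinSet-class].
#' @export
readProteinSet <- function(fasta, labels = NULL, ss = NULL, domains = NULL,
                           setName = basename(fasta)) {
  x <- readFastaSet(fasta, setName = setName)
  ids <- names(x)
  if (!is.null(labels)) {
    lt <- readLabelsTsv(labels)
    x@label <- lt$label[match(ids, lt$id)]
  }
  if (!is.null(ss)) {
    st <- readSsTsv(ss)
    x@ss <- st$ss[match(ids, st$id)]
  }
  if (!is.null(domains)) {
    dt <- readDomainsTsv(domains)
    x@domains <- lapply(ids, function(id) {
      d <- dt[dt$id == id, c("name", "start", "end"), drop = FALSE]
      if (nrow(d) == 0L) NULL else { rownames(d) <- NULL; d }
    })
  }
  validObject(x)
  x
}

#' Filter sequences on length and alphabet validity
#'
#' Applies the corpus validity filters: sequences shorter than `minLen` or
#' longer than `maxLen` residues, or containing any residue outside the 20
#' standard amino-acid letters, are rejected. The bounds are inclusive
#' (a length-100 or length-2000 sequence passes the defaults). Length is
#' checked before the alphabet, so a short sequence with a nonstandard
#' residue reports `too_short`. Selenocysteine (U) and other extended codes
#' count as nonstandard.
#'
#' @param x A [ProteinSet-class].
#' @param minLen,maxLen Inclusive length bounds (defaults 100 and 2000).
#' @return A list of class `FilterReport` with elements `kept` (a
#'   [ProteinSet-class]) and `rejected` (`data.frame(id, reason)` with
#'   reasons `too_short`, `too_long`, `nonstandard_aa`).
#' @examples
#' ps <- proteinSet(c(ok = paste(rep("ACDEFGHIKL", 12), collapse = ""),
#'                    bad = "ACDXG"))
#' filterRecords(ps)$rejected
#' @export
filterRecords <- function(x, minLen = 100L, maxLen = 2000L) {
  w <- Biostrings::width(x@sequences)
  seqs <- .seqStrings(x)
  ok_alpha <- !grepl(sprintf("[^%s]", paste(.AA20, collapse = "")), seqs)
  reason <- rep(NA_character_, length(x))
  reason[w > maxLen] <- "too_long"
  reason[w < minLen] <- "too_short"
  reason[is.na(reason) & !ok_alpha] <- "nonstandard_aa"
  keep <- is.na(reason)
  rejected <- data.frame(id = names(x)[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  out <- list(kept = x[keep], rejected = rejected)
  class(out) <- "FilterReport"
  out
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport: %d kept, %d rejected\n",
              length(x$kept), nrow(x$rejected)))
  if (nrow(x$rejected)) print(table(x$rejected$reason))
  invisible(x)
}

#' One-hot encode a protein sequence
#'
#' Encodes a sequence as an `Lmax` x 20 indicator matrix under the fixed
#' alphabetical ordering of [aminoAlphabet()]. Rows beyond the sequence
#' length are all zero (post-padding).
#'
#' @param x A single sequence as a character string, or a
#'   [ProteinSet-class] of length 1.
#' @param Lmax Padded length of the encoding (model input length).
#' @return A list of class `EncodedSequence` with elements `matrix`
#'   (`Lmax` x 20) and `trueLength`.
#' @examples
#' enc <- oneHot("ACD", Lmax = 5)
#' rowSums(enc$matrix)
#' @export
oneHot <- function(x, Lmax) {
  if (is(x, "ProteinSet")) {
    stopifnot(length(x) == 1L)
    x <- .seqStrings(x)
  }
  s <- toupper(as.character(x))
  L <- nchar(s)
  if (L > Lmax)
    stop(sprintf("sequence length %d exceeds Lmax = %d", L, Lmax), call. = FALSE)
  idx <- match(strsplit(s, "")[[1]], .AA20)
  if (anyNA(idx))
    stop("sequence contains residues outside the standard 20-letter alphabet",
         call. = FALSE)
  m <- matrix(0, nrow = Lmax, ncol = 20L,
              dimnames = list(NULL, .AA20))
  if (L > 0) m[cbind(seq_len(L), idx)] <- 1
  structure(list(matrix = m, trueLength = L), class = "EncodedSequence")
}

#' Decode a one-hot encoding back to a sequence
#'
#' Inverse of [oneHot()] on the non-padded rows.
#'
#' @param enc An `EncodedSequence`.
#' @return The decoded sequence as a character string.
#' @export
decodeOneHot <- function(enc) {
  L <- enc$trueLength
  if (L == 0L) return("")
  idx <- apply(enc$matrix[seq_len(L), , drop = FALSE], 1L, which.max)
  paste(.AA20[idx], collapse = "")
}

# Batch-encode sequences into a (B*Lmax) x 20 matrix, sequence-major rows.
# Used by the network forward pass; errors name the offending record.
.encodeBatch <- function(seqs, Lmax, ids = names(seqs)) {
  B <- length(seqs)
  X <- matrix(0, nrow = B * Lmax, ncol = 20L)
  for (b in seq_len(B)) {
    s <- seqs[[b]]
    L <- nchar(s)
    if (L > Lmax)
      stop(sprintf("sequence '%s' (length %d) exceeds model input length %d",
                   if (!is.null(ids)) ids[b] else b, L, Lmax), call. = FALSE)
    idx <- match(strsplit(s, "")[[1]], .AA20)
    if (anyNA(idx))
      stop(sprintf("sequence '%s' contains a nonstandard residue",
                   if (!is.null(ids)) ids[b] else b), call. = FALSE)
    X[cbind((b - 1L) * Lmax + seq_len(L), idx)] <- 1
  }
  X
}
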