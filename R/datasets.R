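# Corpus assembly: train/test splits, label aggregation, id-based
# de-overlap and the uniform-bin rebalanced subsample used for tuning.

.checkLabeled <- function(x) {
  if (anyNA(x@label))
    stop("every record must carry a numeric label", call. = FALSE)
  ids <- names(x)
  if (anyDuplicated(ids))
    stop("record ids must be unique within a labeled set", call. = FALSE)
  invisible(x)
}

#' Random train/test split of a labeled set
#'
#' Uniform random partition by record under a fixed seed. The test size is
#' `floor(testFraction * n)`; train and test are disjoint by id and jointly
#' cover the input.
#'
#' @param x A labeled [ProteinSet-class] (all labels present, unique ids).
#' @param testFraction Proportion in (0, 1) assigned to the test partition.
#' @param seed Integer seed making the partition reproducible.
#' @return A list of class `SplitResult` with elements `train`, `test`
#'   (both [ProteinSet-class]), `seed` and `testFraction`.
#' @examples
#' ps <- proteinSet(setNames(rep("ACDEFGHIKL", 10), paste0("P", 1:10)),
#'                  label = 1:10)
#' sp <- splitLabeledSet(ps, 0.5, seed = 1)
#' length(sp$test)
#' @export
splitLabeledSet <- function(x, testFraction, seed) {
  .checkLabeled(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be in (0, 1)", call. = FALSE)
  nTest <- floor(testFraction * n)
  testIdx <- .withSeed(seed, sample.int(n, nTest))
  train <- x[setdiff(seq_len(n), testIdx)]
  test <- x[testIdx]
  setName(train) <- paste0(x@setName, ".train")
  setName(test) <- paste0(x@setName, ".test")
  structure(list(train = train, test = test, seed = as.integer(seed),
                 testFraction = testFraction),
            class = "SplitResult")
}

#' @export
print.SplitResult <- function(x, ...) {
  cat(sprintf("SplitResult: %d train / %d test (testFraction = %g, seed = %d)\n",
              length(x$train), length(x$test), x$testFraction, x$seed))
  invisible(x)
}

#' Write a split manifest as two-column TSV (id, partition)
#'
#' @param split A `SplitResult` from [splitLabeledSet()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSplitTsv <- function(split, path) {
  df <- data.frame(
    id = c(names(split$train), names(split$test)),
    partition = c(rep("train", length(split$train)),
                  rep("test", length(split$test))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Rebalanced subsample with uniform label bins
#'
#' Counters label imbalance by binning labels into consecutive
#' `binWidth`-degree bins spanning the observed range (bins anchored at
#' `floor(min/binWidth) * binWidth`) and sampling an equal quota from each
#' non-empty bin without replacement. The quota is `n` divided by the number
#' of non-empty bins; any remainder is distributed one-per-bin in bin order,
#' so bins holding at least their quota contribute counts differing by at
#' most one. Bins with fewer members than their quota contribute all their
#' members (no resampling with replacement) and the shortfall is reported
#' via `message()`.
#'
#' @param x A labeled [ProteinSet-class].
#' @param n Target subsample size; must be at least the number of non-empty
#'   bins.
#' @param binWidth Bin width in degrees Celsius (default 5).
#' @param seed Integer seed.
#' @return A [ProteinSet-class] with at most `n` records.
#' @export
uniformSubsample <- function(x, n, binWidth = 5, seed) {
  .checkLabeled(x)
  if (length(x) == 0L) stop("cannot subsample an empty set", call. = FALSE)
  lab <- x@label
  lo <- floor(min(lab) / binWidth) * binWidth
  bin <- floor((lab - lo) / binWidth)
  binIds <- sort(unique(bin))
  B <- length(binIds)
  if (n < B)
    stop(sprintf("n = %d is below the number of non-empty bins (%d)", n, B),
         call. = FALSE)
  base <- n %/% B
  extra <- n %% B
  quota <- rep(base, B) + c(rep(1L, extra), rep(0L, B - extra))
  keep <- .withSeed(seed, {
    unlist(lapply(seq_len(B), function(i) {
      members <- which(bin == binIds[i])
      take <- min(quota[i], length(members))
      if (take < quota[i])
        message(sprintf("bin [%g, %g) holds %d < quota %d; taking all members",
                        lo + binIds[i] * binWidth, lo + (binIds[i] + 1) * binWidth,
                        length(members), quota[i]))
      if (take == length(members)) members else sample(members, take)
    }))
  })
  out <- x[sort(keep)]
  setName(out) <- paste0(x@setName, ".balanced")
  out
}

#' Aggregate replicate labels by arithmetic mean
#'
#' Collapses a long table of (id, label) measurements to one row per unique
#' id, using the arithmetic mean of that id's values (the convention for
#' proteins with multiple melting-temperature measurements).
#'
#' @param df A `data.frame` with columns `id` and `label`.
#' @return A `data.frame(id, label)` with one row per unique id, in order of
#'   first appearance.
#' @examples
#' aggregateMeanLabel(data.frame(id = c("P1", "P1", "P2"),
#'                               label = c(50, 60, 41)))
#' @export
aggregateMeanLabel <- function(df) {
  if (!all(c("id", "label") %in% names(df)))
    stop("df must have columns 'id' and 'label'", call. = FALSE)
  lab <- df$label
  if (!is.numeric(lab)) {
    lab <- suppressWarnings(as.numeric(lab))
    if (anyNA(lab)) stop("non-numeric label values", call. = FALSE)
  }
  if (anyNA(lab)) stop("missing label values", call. = FALSE)
  ids <- as.character(df$id)
  first <- !duplicated(ids)
  means <- tapply(lab, ids, mean)
  data.frame(id = ids[first], label = as.numeric(means[ids[first]]),
             stringsAsFactors = FALSE)
}

#' Remove records whose ids appear in an exclusion list
#'
#' Id-based de-overlap between data sets (e.g. removing target-task proteins
#' from a pretraining corpus). Order of the remaining records is preserved.
#'
#' @param x A [ProteinSet-class].
#' @param excludeIds Character vector of ids to drop.
#' @return A [ProteinSet-class] without the excluded records.
#' @export
removeOverlap <- function(x, excludeIds) {
  keep <- !(names(x) %in% as.character(excludeIds))
  x[keep]
}
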