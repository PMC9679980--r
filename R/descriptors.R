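# Classical sequence descriptors: 20 families totalling 5,494 features
# under the default parameterization. Parameters are fixed so the printed
# family dimensions hold: k-spaced pair families use gaps 0..5, the
# autocorrelation families use the 8 vendored property scales with 30 lags,
# the pseudo-composition families use lambda = 30, and the sequence-order
# families use 30 lags over 2 residue-distance matrices.

.DESC_DIMS <- c(
  AAC = 20L, DPC = 400L, CKSAAP = 2400L, DDE = 400L, GAAC = 5L,
  CKSAAGP = 150L, GDPC = 25L, GTPC = 125L, Moran = 240L, Geary = 240L,
  NMBroto = 240L, CTDC = 39L, CTDT = 39L, CTDD = 195L, CTriad = 343L,
  KSCTriad = 343L, PAAC = 50L, APAAC = 80L, SOCNumber = 60L, QSOrder = 100L)

.DESC_MINLEN <- c(
  AAC = 1L, DPC = 2L, CKSAAP = 7L, DDE = 2L, GAAC = 1L, CKSAAGP = 7L,
  GDPC = 2L, GTPC = 3L, Moran = 31L, Geary = 31L, NMBroto = 31L, CTDC = 1L,
  CTDT = 2L, CTDD = 1L, CTriad = 3L, KSCTriad = 3L, PAAC = 31L, APAAC = 31L,
  SOCNumber = 31L, QSOrder = 31L)

#' Descriptor family table
#'
#' Names and dimensionalities of the 20 classical descriptor families
#' computed by [computeDescriptors()]. The widths sum to 5,494.
#'
#' @return A `data.frame(family, width, min_length)`.
#' @examples
#' sum(descriptorFamilies()$width)
#' @export
descriptorFamilies <- function() {
  data.frame(family = names(.DESC_DIMS), width = unname(.DESC_DIMS),
             min_length = unname(.DESC_MINLEN), stringsAsFactors = FALSE)
}

.descSeq <- function(x) {
  if (is(x, "ProteinSet")) {
    stopifnot(length(x) == 1L)
    x <- .seqStrings(x)
  }
  s <- toupper(as.character(x))
  idx <- match(strsplit(s, "")[[1]], .AA20)
  if (anyNA(idx))
    stop("sequence contains residues outside the standard 20-letter alphabet",
         call. = FALSE)
  idx
}

.groupIndex <- function(groups) {
  g <- integer(20)
  for (i in seq_along(groups)) g[match(groups[[i]], .AA20)] <- i
  g
}

# ---- individual families (idx = integer residue indices into .AA20) ----

.famAAC <- function(idx) {
  v <- tabulate(idx, 20L) / length(idx)
  stats::setNames(v, paste0("AAC.", .AA20))
}

.kSpacedPairs <- function(idx, k, nSym, symIdx, prefix, symNames) {
  L <- length(symIdx)
  n <- L - k - 1L
  code <- (symIdx[seq_len(n)] - 1L) * nSym + symIdx[seq_len(n) + k + 1L]
  v <- tabulate(code, nSym * nSym) / n
  pairNames <- as.vector(t(outer(symNames, symNames, paste0)))
  stats::setNames(v, sprintf("%s.k%d.%s", prefix, k, pairNames))
}

.famDPC <- function(idx) {
  v <- .kSpacedPairs(idx, 0L, 20L, idx, "DPC", .AA20)
  names(v) <- sub("^DPC\\.k0\\.", "DPC.", names(v))
  v
}

.famCKSAAP <- function(idx, gaps = 0:5) {
  unlist(lapply(gaps, function(k) .kSpacedPairs(idx, k, 20L, idx,
                                                "CKSAAP", .AA20)))
}

.famDDE <- function(idx) {
  L <- length(idx)
  n <- L - 1L
  code <- (idx[seq_len(n)] - 1L) * 20L + idx[seq_len(n) + 1L]
  Dc <- tabulate(code, 400L) / n
  cfrac <- .AA_CODONS / 61
  Tm <- as.vector(t(outer(cfrac, cfrac)))
  Tv <- Tm * (1 - Tm) / n
  v <- (Dc - Tm) / sqrt(Tv)
  pairNames <- as.vector(t(outer(.AA20, .AA20, paste0)))
  stats::setNames(v, paste0("DDE.", pairNames))
}

.famGAAC <- function(idx) {
  g <- .groupIndex(.AA_GROUPS5)[idx]
  v <- tabulate(g, 5L) / length(g)
  stats::setNames(v, paste0("GAAC.", names(.AA_GROUPS5)))
}

.famCKSAAGP <- function(idx, gaps = 0:5) {
  g <- .groupIndex(.AA_GROUPS5)[idx]
  unlist(lapply(gaps, function(k) .kSpacedPairs(idx, k, 5L, g,
                                                "CKSAAGP", names(.AA_GROUPS5))))
}

.famGDPC <- function(idx) {
  g <- .groupIndex(.AA_GROUPS5)[idx]
  v <- .kSpacedPairs(idx, 0L, 5L, g, "GDPC", names(.AA_GROUPS5))
  names(v) <- sub("^GDPC\\.k0\\.", "GDPC.", names(v))
  v
}

.famGTPC <- function(idx) {
  g <- .groupIndex(.AA_GROUPS5)[idx]
  L <- length(g)
  n <- L - 2L
  code <- (g[seq_len(n)] - 1L) * 25L + (g[seq_len(n) + 1L] - 1L) * 5L +
    g[seq_len(n) + 2L]
  v <- tabulate(code, 125L) / n
  gn <- names(.AA_GROUPS5)
  nm <- as.vector(t(outer(gn, as.vector(t(outer(gn, gn, paste, sep = "."))),
                          paste, sep = ".")))
  stats::setNames(v, paste0("GTPC.", nm))
}

.autocorr <- function(idx, nlag, kind) {
  L <- length(idx)
  out <- numeric(0)
  for (sn in names(.AA_SCALES)) {
    p <- .stdScale(.AA_SCALES[[sn]])[idx]
    pbar <- mean(p)
    cdev <- p - pbar
    denMoran <- mean(cdev^2)
    denGeary <- sum(cdev^2) / (L - 1)
    vals <- vapply(seq_len(nlag), function(d) {
      a <- seq_len(L - d)
      switch(kind,
        Moran = if (denMoran == 0) 0 else
          mean(cdev[a] * cdev[a + d]) / denMoran,
        Geary = if (denGeary == 0) 0 else
          (sum((p[a] - p[a + d])^2) / (2 * (L - d))) / denGeary,
        NMBroto = sum(p[a] * p[a + d]) / (L - d))
    }, numeric(1))
    out <- c(out, stats::setNames(vals, sprintf("%s.%s.lag%d", kind, sn,
                                                seq_len(nlag))))
  }
  out
}

.ctdClass <- function(partition, idx) {
  g <- integer(20)
  for (i in 1:3) g[match(partition[[i]], .AA20)] <- i
  g[idx]
}

.famCTDC <- function(idx) {
  out <- numeric(0)
  for (pn in names(.CTD_GROUPS)) {
    cl <- .ctdClass(.CTD_GROUPS[[pn]], idx)
    v <- tabulate(cl, 3L) / length(cl)
    out <- c(out, stats::setNames(v, sprintf("CTDC.%s.g%d", pn, 1:3)))
  }
  out
}

.famCTDT <- function(idx) {
  out <- numeric(0)
  n <- length(idx) - 1L
  for (pn in names(.CTD_GROUPS)) {
    cl <- .ctdClass(.CTD_GROUPS[[pn]], idx)
    a <- cl[seq_len(n)]
    b <- cl[seq_len(n) + 1L]
    t12 <- sum((a == 1 & b == 2) | (a == 2 & b == 1)) / n
    t13 <- sum((a == 1 & b == 3) | (a == 3 & b == 1)) / n
    t23 <- sum((a == 2 & b == 3) | (a == 3 & b == 2)) / n
    out <- c(out, stats::setNames(c(t12, t13, t23),
                                  sprintf("CTDT.%s.%s", pn,
                                          c("t12", "t13", "t23"))))
  }
  out
}

.famCTDD <- function(idx) {
  L <- length(idx)
  out <- numeric(0)
  pts <- c(0, 0.25, 0.50, 0.75, 1)
  for (pn in names(.CTD_GROUPS)) {
    cl <- .ctdClass(.CTD_GROUPS[[pn]], idx)
    for (g in 1:3) {
      pos <- which(cl == g)
      n <- length(pos)
      v <- if (n == 0L) rep(0, 5) else {
        ii <- pmax(1L, ceiling(pts * n))
        pos[ii] / L * 100
      }
      out <- c(out, stats::setNames(v, sprintf("CTDD.%s.g%d.p%d", pn, g,
                                               c(0, 25, 50, 75, 100))))
    }
  }
  out
}

.triadCounts <- function(idx, k, prefix) {
  g <- .groupIndex(.AA_GROUPS7)[idx]
  L <- length(g)
  span <- 2L * (k + 1L)
  n <- L - span
  if (n < 1L)
    stop(sprintf("%s with gap %d needs length > %d", prefix, k, span),
         call. = FALSE)
  i1 <- seq_len(n)
  code <- (g[i1] - 1L) * 49L + (g[i1 + k + 1L] - 1L) * 7L + g[i1 + span]
  v <- tabulate(code, 343L) / n
  gn <- names(.AA_GROUPS7)
  nm <- as.vector(t(outer(gn, as.vector(t(outer(gn, gn, paste, sep = "."))),
                          paste, sep = ".")))
  stats::setNames(v, paste0(prefix, ".", nm))
}

.famCTriad <- function(idx) .triadCounts(idx, 0L, "CTriad")
.famKSCTriad <- function(idx, k = 0L) .triadCounts(idx, k, "KSCTriad")

.paacTheta <- function(idx, scales, lambda) {
  L <- length(idx)
  H <- lapply(scales, function(sn) .stdScale(.AA_SCALES[[sn]])[idx])
  vapply(seq_len(lambda), function(k) {
    a <- seq_len(L - k)
    mean(Reduce(`+`, lapply(H, function(h) (h[a] - h[a + k])^2)) /
           length(H))
  }, numeric(1))
}

.famPAAC <- function(idx, lambda = 30L, w = 0.05) {
  f <- tabulate(idx, 20L) / length(idx)
  theta <- .paacTheta(idx, c("hydropathy", "hydrophilicity",
                             "sidechain_mass"), lambda)
  den <- 1 + w * sum(theta)
  stats::setNames(c(f / den, w * theta / den),
                  c(paste0("PAAC.", .AA20),
                    paste0("PAAC.lambda", seq_len(lambda))))
}

.famAPAAC <- function(idx, lambda = 30L, w = 0.05) {
  L <- length(idx)
  f <- tabulate(idx, 20L) / L
  H <- lapply(c("hydropathy", "hydrophilicity"),
              function(sn) .stdScale(.AA_SCALES[[sn]])[idx])
  tau <- unlist(lapply(seq_len(lambda), function(k) {
    a <- seq_len(L - k)
    vapply(H, function(h) sum(h[a] * h[a + k]) / (L - k), numeric(1))
  }))
  den <- 1 + w * sum(tau)
  stats::setNames(c(f / den, w * tau / den),
                  c(paste0("APAAC.", .AA20),
                    paste0("APAAC.", as.vector(t(outer(seq_len(lambda),
                      c("hydropathy", "hydrophilicity"), function(k, p)
                        paste0(p, ".lag", k)))))))
}

.soTau <- function(idx, D, nlag) {
  L <- length(idx)
  vapply(seq_len(nlag), function(d) {
    a <- seq_len(L - d)
    sum(D[cbind(idx[a], idx[a + d])]^2)
  }, numeric(1))
}

.famSOCNumber <- function(idx, nlag = 30L) {
  mats <- .soDistMatrices()
  out <- numeric(0)
  for (mn in names(mats))
    out <- c(out, stats::setNames(.soTau(idx, mats[[mn]], nlag),
                                  sprintf("SOCNumber.%s.lag%d", mn,
                                          seq_len(nlag))))
  out
}

.famQSOrder <- function(idx, nlag = 30L, w = 0.1) {
  f <- tabulate(idx, 20L) / length(idx)
  mats <- .soDistMatrices()
  out <- numeric(0)
  for (mn in names(mats)) {
    tau <- .soTau(idx, mats[[mn]], nlag)
    den <- 1 + w * sum(tau)
    out <- c(out, stats::setNames(
      c(f / den, w * tau / den),
      c(sprintf("QSOrder.%s.%s", mn, .AA20),
        sprintf("QSOrder.%s.lag%d", mn, seq_len(nlag)))))
  }
  out
}

#' Compute one descriptor family
#'
#' Computes a single family's feature block at its canonical
#' dimensionality. Composition families are frequency-normalized;
#' autocorrelation, pseudo-composition and sequence-order families use the
#' vendored property scales (see `descriptor-data`) with their default lag
#' parameters.
#'
#' @param x A sequence string or a [ProteinSet-class] of length 1.
#' @param family Family name; one of `descriptorFamilies()$family`.
#' @return Named numeric vector of the family's canonical width.
#' @examples
#' computeFamily("AACA", "AAC")[c("AAC.A", "AAC.C")]
#' @export
computeFamily <- function(x, family) {
  family <- match.arg(family, names(.DESC_DIMS))
  idx <- .descSeq(x)
  L <- length(idx)
  if (L < .DESC_MINLEN[[family]])
    stop(sprintf("family %s requires sequence length >= %d (got %d)",
                 family, .DESC_MINLEN[[family]], L), call. = FALSE)
  v <- switch(family,
    AAC = .famAAC(idx), DPC = .famDPC(idx), CKSAAP = .famCKSAAP(idx),
    DDE = .famDDE(idx), GAAC = .famGAAC(idx), CKSAAGP = .famCKSAAGP(idx),
    GDPC = .famGDPC(idx), GTPC = .famGTPC(idx),
    Moran = .autocorr(idx, 30L, "Moran"),
    Geary = .autocorr(idx, 30L, "Geary"),
    NMBroto = .autocorr(idx, 30L, "NMBroto"),
    CTDC = .famCTDC(idx), CTDT = .famCTDT(idx), CTDD = .famCTDD(idx),
    CTriad = .famCTriad(idx), KSCTriad = .famKSCTriad(idx),
    PAAC = .famPAAC(idx), APAAC = .famAPAAC(idx),
    SOCNumber = .famSOCNumber(idx), QSOrder = .famQSOrder(idx))
  stopifnot(length(v) == .DESC_DIMS[[family]])
  v
}

#' Compute all 20 descriptor families for one sequence
#'
#' Evaluates every family with its default parameterization and returns the
#' ordered per-family blocks; the concatenated vector has exactly 5,494
#' values. Deterministic: the same sequence always yields the same vector.
#'
#' @param x A sequence string or a [ProteinSet-class] of length 1; length
#'   must be at least 31 residues so the 30-lag families are defined (the
#'   corpus filters guarantee 100-2000).
#' @return A [DescriptorVector-class].
#' @examples
#' dv <- computeDescriptors(paste(rep("ACDEFGHIKLMNPQRSTVWY", 10),
#'                                collapse = ""))
#' length(descriptorValues(dv))
#' @export
computeDescriptors <- function(x) {
  blocks <- lapply(names(.DESC_DIMS), function(fam) computeFamily(x, fam))
  names(blocks) <- names(.DESC_DIMS)
  new("DescriptorVector", blocks = blocks)
}

#' @describeIn computeDescriptors Flat named numeric vector (length 5,494)
#'   of a descriptor object.
#' @param dv A [DescriptorVector-class].
#' @export
descriptorValues <- function(dv) unlist(dv@blocks, use.names = TRUE)

#' @describeIn computeDescriptors The per-family blocks of a descriptor
#'   object.
#' @export
descriptorBlocks <- function(dv) dv@blocks

setMethod("length", "DescriptorVector", function(x)
  sum(lengths(x@blocks)))

setMethod("show", "DescriptorVector", function(object) {
  cat(sprintf("DescriptorVector: %d families, %d features\n",
              length(object@blocks), length(object)))
})

#' Descriptor matrix for a protein set
#'
#' One row per record, 5,494 family-prefixed columns.
#'
#' @param x A [ProteinSet-class].
#' @return Numeric matrix with row names set to record ids.
#' @export
descriptorMatrix <- function(x) {
  seqs <- .seqStrings(x)
  rows <- lapply(seqs, function(s) descriptorValues(computeDescriptors(s)))
  m <- do.call(rbind, rows)
  rownames(m) <- names(x)
  m
}

#' Write a descriptor matrix as TSV
#'
#' @param m Matrix from [descriptorMatrix()].
#' @param path Output path (id column + named feature columns).
#' @return Invisibly, `path`.
#' @export
writeDescriptorTsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Standard scaling of a feature matrix
#'
#' `fitScaler` records per-column mean and standard deviation;
#' `applyScaler` transforms a matrix to zero mean and unit variance per
#' column. Constant columns (sd = 0) map to 0. Fitting on the combined
#' train and test matrix reproduces the historical all-samples protocol;
#' fitting on the training matrix only (recommended) avoids information
#' leaking from the test partition into the scaling.
#'
#' @param m Numeric matrix (samples x features), at least 2 rows for `fit`.
#' @param stats A `ScalingStats` from `fitScaler`.
#' @return `fitScaler`: a list of class `ScalingStats` with `mean` and `sd`;
#'   `applyScaler`: the scaled matrix.
#' @examples
#' sc <- fitScaler(cbind(a = c(1, 3), b = c(5, 5)))
#' applyScaler(cbind(a = c(1, 3), b = c(5, 5)), sc)
#' @name scaler
NULL

#' @rdname scaler
#' @export
fitScaler <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L)
    stop("need at least 2 samples to fit a scaler", call. = FALSE)
  structure(list(mean = colMeans(m), sd = apply(m, 2L, stats::sd)),
            class = "ScalingStats")
}

#' @rdname scaler
#' @export
applyScaler <- function(m, stats) {
  m <- as.matrix(m)
  if (ncol(m) != length(stats$mean))
    stop("matrix width does not match the fitted scaler", call. = FALSE)
  s <- ifelse(stats$sd == 0, 1, stats$sd)
  out <- sweep(sweep(m, 2L, stats$mean, "-"), 2L, s, "/")
  out[, stats$sd == 0] <- 0
  out
}
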