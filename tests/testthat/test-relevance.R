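test_that("a constant predictor yields an all-zero profile with no significant positions", {
  net <- makeConstantNet(5)
  s <- randomSeqs(1, 40, seed = 1)
  p <- occlusionProfile(net, s, width = 5)
  expect_equal(length(p@scores), 40L)
  expect_true(all(p@scores == 0))
  expect_true(all(p@z == 0))
  expect_equal(sum(p@significant), 0L)
})

test_that("profiles have the sequence length and per-protein z is standardized", {
  net <- makeCountingNet()
  for (len in c(30L, 47L)) {
    s <- randomSeqs(1, len, seed = len)
    p <- occlusionProfile(net, s, width = 5)
    expect_length(p@scores, len)
    if (sd(p@scores) > 0) {
      expect_equal(mean(p@z), 0, tolerance = 1e-10)
      expect_equal(sd(p@z), 1, tolerance = 1e-10)
    }
  }
})

test_that("occlusion of a surrogate counting model matches the closed form", {
  # prediction = 100 + 10 * count(W); a single W at position 21 of 41 As:
  # every window covering the W predicts 100 instead of 110, so the
  # residue score is -(width - |i - 21|) / (width * 11) near the W and 0
  # elsewhere, with the minimum exactly at the W.
  net <- makeCountingNet(letter = "W", base = 100, scale = 10)
  s <- paste0(strrep("A", 20), "W", strrep("A", 20))
  width <- 5L
  p <- occlusionProfile(net, s, width = width)
  i <- seq_len(41)
  expected <- -pmax(0, width - abs(i - 21)) / (width * 11)
  expect_equal(p@scores, expected, tolerance = 1e-10)
  expect_equal(which.min(p@scores), 21L)
  expect_true(all(p@scores[abs(i - 21) >= width] == 0))
  expect_true(p@significant[21])
})

test_that("occlusion preconditions are enforced", {
  net <- makeCountingNet(Lmax = 64L)
  expect_error(occlusionProfile(net, "ACDEF", width = 5), "smaller than")
  expect_error(occlusionProfile(net, strrep("A", 60), width = 5), "exceeds")
  zero <- makeConstantNet(0)
  expect_error(occlusionProfile(zero, randomSeqs(1, 30, seed = 2)),
               "undefined")
})

test_that("significant sets are stable across occlusion widths on planted signal", {
  net <- makeCountingNet(Lmax = 128L)
  s <- paste0(strrep("A", 44), "W", strrep("A", 44))
  ov <- stabilityCheck(net, s, widths = c(2L, 5L, 10L, 20L))
  expect_equal(unname(diag(ov)), rep(1, 4))
  expect_true(all(ov > 0))  # every width pair overlaps on the planted W
  # constant model: all sets empty, Jaccard defined as 1
  ovEmpty <- stabilityCheck(makeConstantNet(7, Lmax = 128L), s,
                            widths = c(2L, 5L))
  expect_true(all(ovEmpty == 1))
})

test_that("surrogate score profiles flag the expected fraction at |z| > 2", {
  set.seed(77)
  p <- relevanceProfileFromScores("big", rnorm(10000), width = 5)
  frac <- mean(p@significant)
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.06)
})

test_that("hypergeometric enrichment matches the combinatorial closed form", {
  # urn: N = 100, K = 20 category positions, n_sig = 10 draws, k = 8
  prof <- relevanceProfileFromScores("p1", rep(0, 100), width = 5)
  prof@significant <- c(rep(TRUE, 10), rep(FALSE, 90))
  ann <- paste0(strrep("A", 8), strrep("B", 2),   # 8 of 10 significant are A
                strrep("A", 12), strrep("B", 78))
  res <- enrichCategories(list(prof), stats::setNames(ann, "p1"),
                          alphabet = c("A", "B"))
  rowA <- res[res$category == "A", ]
  expect_equal(rowA$k, 8)
  expect_equal(rowA$K, 20)
  expect_equal(rowA$N, 100)
  pOverOracle <- sum(vapply(8:10, function(j)
    choose(20, j) * choose(80, 10 - j), numeric(1))) / choose(100, 10)
  expect_equal(rowA$p_over, pOverOracle, tolerance = 1e-12)
  expect_equal(rowA$verdict, "enriched")
})

test_that("extreme depletion has the bare lower-tail probability", {
  prof <- relevanceProfileFromScores("p1", rep(0, 30), width = 5)
  prof@significant <- c(rep(TRUE, 6), rep(FALSE, 24))
  ann <- paste0(strrep("B", 6), strrep("A", 12), strrep("B", 12))  # k = 0
  res <- enrichCategories(list(prof), stats::setNames(ann, "p1"),
                          alphabet = c("A", "B"))
  rowA <- res[res$category == "A", ]
  expect_equal(rowA$k, 0)
  expect_equal(rowA$p_under, choose(18, 6) / choose(30, 6), tolerance = 1e-12)
  expect_lt(rowA$p_under, rowA$p_over)
  expect_equal(rowA$verdict, "depleted")
})

test_that("unannotated positions are excluded from all enrichment counts", {
  prof <- relevanceProfileFromScores("p1", rep(0, 20), width = 5)
  prof@significant <- rep(c(TRUE, FALSE), 10)
  ann <- paste0(strrep("A", 10), strrep("?", 10))
  res <- enrichCategories(list(prof), stats::setNames(ann, "p1"),
                          alphabet = c("A", "B"))
  expect_equal(unique(res$N), 10)
  expect_equal(res[res$category == "A", "K"], 10)
  expect_equal(unique(res$n_sig), 5)
  mismatch <- stats::setNames("AAA", "p1")
  expect_error(enrichCategories(list(prof), mismatch, c("A")), "p1")
})

test_that("domain coverage and its window control reproduce the hand-worked instance", {
  # L = 20, domain [6,10], significant {6,7,13}: coverage 2/5; outside
  # segments of length 5 and 10 admit 1 + 6 windows of length 5, one
  # significant position outside: control = (1/7)/5 = 1/35
  prof <- relevanceProfileFromScores("p1", rep(0, 20), width = 5)
  prof@significant <- seq_len(20) %in% c(6, 7, 13)
  cov <- domainCoverage(prof, data.frame(name = "d", start = 6L, end = 10L))
  expect_true(cov$eligible)
  expect_equal(cov$coverage, 0.4)
  expect_equal(cov$control, 1 / 35, tolerance = 1e-12)
  # enumeration oracle for the control's window count
  segs <- list(1:5, 11:20)
  nWin <- sum(vapply(segs, function(s) max(0L, length(s) - 5L + 1L),
                     integer(1)))
  expect_equal(nWin, 7L)
})

test_that("domain coverage edge cases: full coverage, ineligible length, no control window", {
  prof <- relevanceProfileFromScores("p1", rep(0, 20), width = 5)
  prof@significant <- seq_len(20) %in% 6:10
  cov <- domainCoverage(prof, data.frame(name = "full", start = 6L, end = 10L))
  expect_equal(cov$coverage, 1)
  tooLong <- domainCoverage(prof, data.frame(name = "big", start = 1L,
                                             end = 11L))
  expect_false(tooLong$eligible)
  expect_true(is.na(tooLong$coverage))
  # domain of half the length leaves no full outside window
  prof2 <- relevanceProfileFromScores("p2", rep(0, 12), width = 5)
  prof2@significant <- rep(FALSE, 12)
  noWin <- domainCoverage(prof2, data.frame(name = "d", start = 4L, end = 9L))
  expect_true(noWin$eligible)
  expect_true(is.na(noWin$control))
})

test_that("under random significance coverage is unbiased and the control matches window enumeration", {
  set.seed(101)
  L <- 200
  density <- 20 / L
  covs <- numeric(1000)
  for (r in seq_len(1000)) {
    sig <- rep(FALSE, L)
    sig[sample(L, 20)] <- TRUE
    prof <- relevanceProfileFromScores("r", rep(0, L), width = 5)
    prof@significant <- sig
    d <- sample(10:40, 1)
    s <- sample(L - d, 1)
    cov <- domainCoverage(prof, data.frame(name = "d", start = s,
                                           end = s + d - 1L))
    covs[r] <- cov$coverage
    # enumeration oracle for the sliding-window control: list every
    # full-length window in the outside segments explicitly
    wins <- list()
    for (seg in list(seq_len(s - 1L),
                     if (s + d <= L) (s + d):L else integer(0))) {
      if (length(seg) >= d)
        for (w0 in seq_len(length(seg) - d + 1L))
          wins[[length(wins) + 1L]] <- seg[w0:(w0 + d - 1L)]
    }
    sigOut <- sum(sig[-(s:(s + d - 1L))])
    expect_equal(cov$control, (sigOut / length(wins)) / d, tolerance = 1e-12)
  }
  se <- sd(covs) / sqrt(length(covs))
  expect_lt(abs(mean(covs) - density), 3 * se)
})

test_that("domain selection thresholds and orders by coverage", {
  cov <- data.frame(name = c("a", "b", "c"), start = 1, end = 2, length = 2,
                    eligible = TRUE, coverage = c(0.4, 0.29, 0.31),
                    control = 0)
  expect_equal(selectDomains(cov, 0.30), c("a", "c"))
  expect_equal(selectDomains(cov, 0), c("a", "c", "b"))
  expect_equal(selectDomains(cov[0, ]), character(0))
})

test_that("profile TSVs round-trip through the workflow reader", {
  dir <- withr::local_tempdir()
  net <- makeCountingNet()
  x <- proteinSet(c(q1 = paste0(strrep("A", 15), "W", strrep("A", 15))))
  p <- occlusionProfile(net, x, width = 5)
  f <- writeProfilesTsv(list(p), x, file.path(dir, "prof.tsv"))
  back <- ThermoCNN:::.readProfilesForWf(f)
  expect_equal(back[["q1"]]@scores, p@scores)
  expect_equal(back[["q1"]]@significant, p@significant)
})
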