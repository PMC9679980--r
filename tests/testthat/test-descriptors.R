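test_that("amino-acid composition counts frequencies", {
  v <- computeFamily("AACA", "AAC")
  expect_equal(sum(v), 1)
  expect_equal(unname(v["AAC.A"]), 0.75)
  expect_equal(unname(v["AAC.C"]), 0.25)
})

test_that("grouped composition maps a homopolymer to a single group", {
  v <- computeFamily("AAAA", "GAAC")
  expect_equal(unname(v["GAAC.aliphatic"]), 1)
  expect_equal(sum(v), 1)
})

test_that("k-spaced pair composition spans gaps 0..5 at width 2400", {
  s <- randomSeqs(1, 120, seed = 2)
  v <- computeFamily(s, "CKSAAP")
  expect_length(v, 2400L)
  # each gap block is a normalized pair distribution
  for (k in 0:5) {
    blk <- v[grepl(sprintf("^CKSAAP\\.k%d\\.", k), names(v))]
    expect_length(blk, 400L)
    expect_equal(sum(blk), 1)
  }
})

test_that("every family realizes its canonical width for lengths 100, 477 and 2000", {
  fams <- descriptorFamilies()
  for (len in c(100L, 477L, 2000L)) {
    s <- randomSeqs(1, len, seed = len)
    for (i in seq_len(nrow(fams))) {
      v <- computeFamily(s, fams$family[i])
      expect_length(v, fams$width[i])
      expect_false(anyNA(v))
    }
  }
})

test_that("the full vector concatenates to exactly 5494 values, deterministically", {
  s <- randomSeqs(1, 200, seed = 9)
  dv <- computeDescriptors(s)
  expect_equal(length(dv), 5494L)
  expect_equal(unname(vapply(descriptorBlocks(dv), length, integer(1))),
               descriptorFamilies()$width)
  expect_identical(descriptorValues(dv),
                   descriptorValues(computeDescriptors(s)))
})

test_that("composition families are distributions; short sequences hit the lag bound", {
  s <- randomSeqs(1, 150, seed = 3)
  for (fam in c("AAC", "DPC", "GAAC", "GDPC", "GTPC"))
    expect_equal(sum(computeFamily(s, fam)), 1, tolerance = 1e-12)
  expect_error(computeFamily(strrep("ACDEF", 5), "Moran"), ">= 31")
  expect_error(computeDescriptors(strrep("ACDEF", 5)), ">= 31")
})

test_that("autocorrelation of a homopolymer degenerates to zero (no property variance)", {
  s <- strrep("A", 60)
  expect_true(all(computeFamily(s, "Moran") == 0))
  expect_true(all(computeFamily(s, "Geary") == 0))
})

test_that("shuffling a sequence preserves composition but changes lag-based families", {
  s <- randomSeqs(1, 120, seed = 4)
  shuffled <- ThermoCNN:::.withSeed(99,
    paste(sample(strsplit(s, "")[[1]]), collapse = ""))
  expect_equal(computeFamily(s, "AAC"), computeFamily(shuffled, "AAC"))
  expect_equal(computeFamily(s, "GAAC"), computeFamily(shuffled, "GAAC"))
  expect_false(isTRUE(all.equal(computeFamily(s, "Moran"),
                                computeFamily(shuffled, "Moran"))))
  expect_false(isTRUE(all.equal(computeFamily(s, "SOCNumber"),
                                computeFamily(shuffled, "SOCNumber"))))
})

test_that("standard scaling centers and rescales; constant columns map to zero", {
  m <- cbind(a = c(1, 3), b = c(5, 5))
  sc <- fitScaler(m)
  out <- applyScaler(m, sc)
  expect_equal(unname(out[, "a"]), (c(1, 3) - 2) / sd(c(1, 3)))
  expect_equal(unname(out[, "a"]), c(-1, 1) / sqrt(2))
  expect_equal(unname(out[, "b"]), c(0, 0))
  expect_error(fitScaler(m[1, , drop = FALSE]), "at least 2")
})

test_that("train-only scaling leaves the test distribution unstandardized, joint fit does not", {
  set.seed(8)
  train <- matrix(rnorm(40, 10, 2), 20, 2)
  test <- matrix(rnorm(40, 12, 2), 20, 2)
  scTrain <- fitScaler(train)
  scaledTrain <- applyScaler(train, scTrain)
  expect_equal(unname(colMeans(scaledTrain)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(scaledTrain, 2, sd)), c(1, 1), tolerance = 1e-10)
  # the historical all-samples protocol standardizes the pooled matrix
  pooled <- rbind(train, test)
  scaledPooled <- applyScaler(pooled, fitScaler(pooled))
  expect_equal(unname(colMeans(scaledPooled)), c(0, 0), tolerance = 1e-10)
  # under a train-only fit the shifted test block keeps its offset
  expect_gt(mean(applyScaler(test, scTrain)), 0.5)
})

test_that("descriptor matrices carry ids and family-prefixed column names", {
  x <- proteinSet(randomSeqs(3, 100, seed = 6), ids = c("a", "b", "c"))
  m <- descriptorMatrix(x)
  expect_equal(dim(m), c(3L, 5494L))
  expect_equal(rownames(m), c("a", "b", "c"))
  expect_true(all(grepl("^(AAC|DPC|CKSAAP|DDE|GAAC|CKSAAGP|GDPC|GTPC|Moran|Geary|NMBroto|CTDC|CTDT|CTDD|CTriad|KSCTriad|PAAC|APAAC|SOCNumber|QSOrder)\\.",
                        colnames(m))))
})
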