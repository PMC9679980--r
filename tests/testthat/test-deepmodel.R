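test_that("flatten width follows the pooling arithmetic, by formula and by built network", {
  expect_equal(flattenDim(modelConfig()), 20480L)
  expect_equal(flattenDim(modelConfig(inputLength = 128, filters = 16,
                                      poolSize = 8, poolStride = 8)),
               16L * (floor((128 - 8) / 8) + 1L))
  expect_equal(flattenDim(modelConfig(inputLength = 100, filters = 1,
                                      poolSize = 100, poolStride = 1)), 1L)
  # property: realized representation width equals the closed form
  set.seed(2)
  for (i in 1:5) {
    cfg <- modelConfig(inputLength = sample(40:90, 1),
                       filters = sample(2:6, 1),
                       kernelSize = sample(c(3, 5), 1),
                       poolSize = sample(4:10, 1),
                       poolStride = sample(2:6, 1),
                       denseSizes = 8, seed = i)
    net <- buildThermoNet(cfg)
    reps <- extractRepresentation(net, randomSeqs(2, 35, seed = i))
    expect_equal(ncol(reps), flattenDim(cfg))
  }
})

test_that("configuration invariants reject bad architectures", {
  expect_error(modelConfig(nBlocks = 4), "nBlocks")
  expect_error(modelConfig(nBlocks = 0), "nBlocks")
  expect_error(modelConfig(inputLength = 40, poolSize = 50), "poolSize")
  expect_error(modelConfig(dropout = 1), "dropout")
})

test_that("training reduces the loss on an overfittable memorization task", {
  x <- proteinSet(randomSeqs(20, 40, seed = 7),
                  label = seq(20, 60, length.out = 20))
  net <- buildThermoNet(tinyConfig())
  fit <- trainThermoNet(net, x, trainConfig(epochs = 30, batchSize = 10,
                                            learningRate = 3e-3, seed = 1))
  expect_lt(fit$history$train_loss[30], fit$history$train_loss[1])
  expect_equal(nrow(fit$history), 30L)
})

test_that("constant labels are matched to within a degree for nearly all records", {
  x <- proteinSet(randomSeqs(100, 40, seed = 8), label = rep(42, 100))
  net <- buildThermoNet(tinyConfig(seed = 3))
  fit <- trainThermoNet(net, x, trainConfig(epochs = 15, batchSize = 32,
                                            seed = 2))
  pred <- predict(fit$model, x)
  expect_gte(mean(abs(pred - 42) <= 1), 0.9)
})

test_that("fixed seeds reproduce the first-epoch loss exactly", {
  x <- proteinSet(randomSeqs(30, 40, seed = 9), label = rnorm(30, 40, 5))
  run <- function() {
    net <- buildThermoNet(tinyConfig(seed = 5))
    trainThermoNet(net, x, trainConfig(epochs = 2, batchSize = 8,
                                       seed = 11))$history$train_loss
  }
  expect_equal(run(), run(), tolerance = 1e-12)
})

test_that("training errors are informative for empty data and oversized sequences", {
  net <- buildThermoNet(tinyConfig())
  expect_error(trainThermoNet(net, proteinSet(character(0)), trainConfig()),
               "non-empty")
  bad <- proteinSet(c(TOOLONG = strrep("A", 80)), label = 30)
  expect_error(trainThermoNet(net, bad, trainConfig()), "TOOLONG")
})

test_that("transfer modes flag the right groups and from_scratch reinitializes", {
  net <- buildThermoNet(tinyConfig())
  wg <- weightGroups(net)
  expect_setequal(wg$tag[wg$group %in% c("conv_entry", "block1")],
                  "pre_flatten")
  expect_setequal(wg$tag[wg$group %in% c("dense1", "output")],
                  "post_flatten")
  frozenAll <- setTransferMode(net, "frozen_all")
  expect_false(any(weightGroups(frozenAll)$trainable))
  frozenCnn <- setTransferMode(net, "frozen_cnn")
  wg <- weightGroups(frozenCnn)
  expect_false(any(wg$trainable[wg$tag == "pre_flatten"]))
  expect_true(all(wg$trainable[wg$tag == "post_flatten"]))
  tuneAll <- setTransferMode(frozenAll, "tune_all")
  expect_true(all(weightGroups(tuneAll)$trainable))
  expect_identical(modelWeights(tuneAll), modelWeights(net))
  scratch <- setTransferMode(net, "from_scratch", seed = 99)
  expect_false(identical(modelWeights(scratch)$conv_entry,
                         modelWeights(net)$conv_entry))
  expect_error(setTransferMode(net, "nonsense"), "mode must be")
})

test_that("frozen groups are bit-identical after fine-tuning and representations stable", {
  x <- proteinSet(randomSeqs(40, 40, seed = 12), label = rnorm(40, 45, 8))
  base <- buildThermoNet(tinyConfig(seed = 6))
  pre <- trainThermoNet(base, x, trainConfig(epochs = 3, batchSize = 16,
                                             seed = 1))$model
  target <- proteinSet(randomSeqs(30, 40, seed = 13), label = rnorm(30, 60, 5))
  repsBefore <- extractRepresentation(pre, target)

  frozenCnn <- setTransferMode(pre, "frozen_cnn")
  tuned <- trainThermoNet(frozenCnn, target,
                          trainConfig(epochs = 4, batchSize = 16,
                                      seed = 2))$model
  expect_identical(modelWeights(tuned, c("conv_entry", "block1")),
                   modelWeights(pre, c("conv_entry", "block1")))
  expect_identical(extractRepresentation(tuned, target), repsBefore)
  # the head did move
  expect_false(identical(modelWeights(tuned)$output,
                         modelWeights(pre)$output))

  frozenAll <- setTransferMode(pre, "frozen_all")
  untouched <- trainThermoNet(frozenAll, target,
                              trainConfig(epochs = 2, batchSize = 16,
                                          seed = 3, warmStart = FALSE))$model
  expect_identical(modelWeights(untouched), modelWeights(pre))
  expect_identical(predict(untouched, target), predict(pre, target))

  tuneAll <- trainThermoNet(setTransferMode(pre, "tune_all"), target,
                            trainConfig(epochs = 2, batchSize = 16,
                                        seed = 4))$model
  expect_false(identical(extractRepresentation(tuneAll, target), repsBefore))
})

test_that("predictions are pure, order-invariant and linear-head-consistent", {
  net <- buildThermoNet(tinyConfig(seed = 2))
  seqs <- randomSeqs(6, 40, seed = 14)
  names(seqs) <- paste0("s", 1:6)
  p <- predict(net, seqs)
  expect_equal(unname(p[1]), unname(predict(net, seqs[c(1, 1)])[1]))
  expect_equal(unname(predict(net, seqs[c(1, 1)])[1]),
               unname(predict(net, seqs[c(1, 1)])[2]))
  shuffled <- seqs[c(4, 2, 6, 1, 3, 5)]
  expect_equal(predict(net, shuffled), p[names(shuffled)])
  # zero output layer forces zero predictions
  zero <- net
  i <- length(zero@head)
  zero@head[[i]]$W[] <- 0
  zero@head[[i]]$b[] <- 0
  expect_equal(unname(predict(zero, seqs)), rep(0, 6))
  expect_error(predict(net, c(BAD = "ACDEFBZ")), "nonstandard")
})

test_that("checkpoints round-trip with a JSON sidecar describing the architecture", {
  dir <- withr::local_tempdir()
  net <- buildThermoNet(tinyConfig(seed = 4))
  path <- file.path(dir, "model.rds")
  saveThermoNet(net, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$flattenDim, flattenDim(net))
  back <- loadThermoNet(path)
  seqs <- randomSeqs(3, 30, seed = 1)
  expect_identical(predict(back, seqs), predict(net, seqs))
})
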