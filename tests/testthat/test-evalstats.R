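test_that("regression metrics match hand computation on the 3-point example", {
  m <- regressionMetrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$r2, 0.5)              # SS_res = 1, SS_tot = 2
  expect_equal(m$rmse, sqrt(1 / 3))
  perfect <- regressionMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$pearson, 1)
  expect_equal(perfect$spearman, 1)
  meanPred <- regressionMetrics(c(1, 2, 3), rep(2, 3))
  expect_equal(meanPred$r2, 0)
})

test_that("metrics agree with a brute-force reference on random instances", {
  ref <- function(y, p) {
    list(r2 = 1 - sum((y - p)^2) / sum((y - mean(y))^2),
         rmse = sqrt(sum((y - p)^2) / length(y)),
         pearson = sum((y - mean(y)) * (p - mean(p))) /
           sqrt(sum((y - mean(y))^2) * sum((p - mean(p))^2)),
         spearman = {
           ry <- rank(y); rp <- rank(p)
           sum((ry - mean(ry)) * (rp - mean(rp))) /
             sqrt(sum((ry - mean(ry))^2) * sum((rp - mean(rp))^2))
         })
  }
  set.seed(10)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    y <- rnorm(n)
    p <- y + rnorm(n, 0, runif(1, 0.1, 2))
    m <- regressionMetrics(y, p)
    r <- ref(y, p)
    expect_equal(m$r2, r$r2, tolerance = 1e-10)
    expect_equal(m$rmse, r$rmse, tolerance = 1e-10)
    expect_equal(m$pearson, r$pearson, tolerance = 1e-10)
    expect_equal(m$spearman, r$spearman, tolerance = 1e-10)
  }
  expect_error(regressionMetrics(1:3, 1:4), "equal length")
  expect_true(is.na(regressionMetrics(c(2, 2, 2), c(1, 2, 3))$r2))
})

test_that("Welch t matches the closed form and its conventions", {
  w <- welchT(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1 / sqrt(1 / 3 + 1 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4)
  same <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)
  degenerate <- welchT(c(5, 5), c(5, 5))
  expect_equal(degenerate$p_two_sided, 1)
})

test_that("Welch t is antisymmetric and p decreases with mean separation", {
  a <- rnorm(10)
  set.seed(3)
  b <- rnorm(10)
  expect_equal(welchT(a, b)$t, -welchT(b, a)$t)
  expect_equal(welchT(a, b)$p_two_sided, welchT(b, a)$p_two_sided)
  ps <- vapply(c(0, 0.5, 1, 2, 4),
               function(d) welchT(a, b + d)$p_two_sided, numeric(1))
  expect_true(all(diff(ps[-1]) < 0))
})

test_that("random search exhausts a small space and finds the optimum", {
  res <- randomSearch(list(x = 1:5), function(cfg) (cfg$x - 3)^2,
                      budget = 5, seed = 1)
  expect_equal(nrow(res), 5L)
  expect_setequal(res$x, 1:5)
  expect_equal(res$x[1], 3)
  res2 <- randomSearch(list(x = 1:5, y = c(0.1, 0.2)),
                       function(cfg) (cfg$x - 3)^2 + cfg$y,
                       budget = 4, seed = 9)
  res3 <- randomSearch(list(x = 1:5, y = c(0.1, 0.2)),
                       function(cfg) (cfg$x - 3)^2 + cfg$y,
                       budget = 4, seed = 9)
  expect_identical(res2, res3)
  expect_error(randomSearch(list(x = 1:2), identity, budget = 3, seed = 1),
               "exceeds")
})

test_that("greedy search solves separable objectives in one sweep and never regresses", {
  space <- list(x = 1:5, y = 1:5)
  evals <- 0
  obj <- function(cfg) { evals <<- evals + 1; (cfg$x - 4)^2 + (cfg$y - 2)^2 }
  out <- greedySearch(space, list(x = 1, y = 5), obj)
  expect_equal(out$config$x, 4)
  expect_equal(out$config$y, 2)
  expect_equal(out$score, 0)
  # enumerate to confirm the sweep found the global optimum
  grid <- expand.grid(x = 1:5, y = 1:5)
  expect_equal(min((grid$x - 4)^2 + (grid$y - 2)^2), out$score)
  # evaluation budget: sweeps x sum of candidate counts (+1 for the start)
  sweeps <- ceiling((out$evaluations - 1) / sum(lengths(space) - 1))
  expect_lte(out$evaluations, 1 + sweeps * sum(lengths(space)))
  # starting at the optimum is a fixed point
  atOpt <- greedySearch(space, list(x = 4, y = 2), obj)
  expect_equal(atOpt$config, list(x = 4, y = 2))
  # a rugged objective never returns something worse than the start
  obj2 <- function(cfg) sin(cfg$x * 2.7) + cos(cfg$y * 1.3)
  start <- list(x = 3, y = 3)
  out2 <- greedySearch(space, start, obj2)
  expect_lte(out2$score, obj2(start))
})

test_that("the classical-regression harness predicts through established fits", {
  skip_if_not_installed("glmnet")
  skip_if_not_installed("rpart")
  set.seed(5)
  x <- matrix(rnorm(600), 100, 6)
  y <- 2 * x[, 1] - x[, 2] + rnorm(100, 0, 0.2)
  xt <- matrix(rnorm(120), 20, 6)
  yt <- 2 * xt[, 1] - xt[, 2]
  for (method in c("ridge", "elastic_net", "tree")) {
    pred <- classicalRegression(x, y, xt, method = method)
    expect_length(pred, 20L)
    expect_true(regressionMetrics(yt, pred)$r2 > 0.2)
  }
})
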