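# Regression metrics, Welch's t comparison of repeated runs, random and
# greedy hyperparameter search, and a thin harness over classical
# regression models.

#' Regression metrics
#'
#' Coefficient of determination (`1 - SS_res/SS_tot`), root mean squared
#' error, and Pearson and Spearman (average-rank ties) correlations. With a
#' constant truth vector the correlations and R2 are undefined and reported
#' as `NA`.
#'
#' @param yTrue,yPred Numeric vectors of equal length (at least 2).
#' @return A list of class `MetricReport` with `r2`, `rmse`, `pearson`,
#'   `spearman` and `n`.
#' @examples
#' regressionMetrics(c(1, 2, 3), c(1, 2, 4))
#' @export
regressionMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length", call. = FALSE)
  n <- length(yTrue)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  ssRes <- sum((yTrue - yPred)^2)
  ssTot <- sum((yTrue - mean(yTrue))^2)
  constant <- ssTot == 0
  structure(list(
    r2 = if (constant) NA_real_ else 1 - ssRes / ssTot,
    rmse = sqrt(mean((yTrue - yPred)^2)),
    pearson = if (constant || stats::sd(yPred) == 0) NA_real_
              else stats::cor(yTrue, yPred),
    spearman = if (constant || stats::sd(yPred) == 0) NA_real_
               else stats::cor(yTrue, yPred, method = "spearman"),
    n = n), class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf("MetricReport (n = %d): R2 = %.4f, RMSE = %.3f, Pearson = %.4f, Spearman = %.4f\n",
              x$n, x$r2, x$rmse, x$pearson, x$spearman))
  invisible(x)
}

#' Welch's unequal-variance t-test between two runs
#'
#' Thin wrapper around [stats::t.test] with `var.equal = FALSE`
#' (Welch-Satterthwaite degrees of freedom), augmented with the one-sided
#' p-value for the observed direction. When both samples are constant and
#' equal the comparison is degenerate and `p = 1` is returned by
#' convention (`t = 0`).
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @return A list of class `WelchT` with `t`, `df`, `p_two_sided`,
#'   `p_one_sided`.
#' @examples
#' welchT(c(1, 2, 3), c(2, 3, 4))
#' @export
welchT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 values", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(structure(list(t = 0, df = NA_real_, p_two_sided = 1,
                            p_one_sided = 0.5), class = "WelchT"))
    return(structure(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                          p_two_sided = 0, p_one_sided = 0),
                     class = "WelchT"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  t <- unname(tt$statistic)
  df <- unname(tt$parameter)
  structure(list(t = t, df = df, p_two_sided = tt$p.value,
                 p_one_sided = stats::pt(-abs(t), df)),
            class = "WelchT")
}

#' @export
print.WelchT <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, two-sided p = %.4g\n",
              x$t, x$df, x$p_two_sided))
  invisible(x)
}

.expandConfig <- function(space, flat) {
  stats::setNames(lapply(seq_along(space),
                         function(j) space[[j]][flat[j]]), names(space))
}

#' Random hyperparameter search
#'
#' Draws `budget` distinct configurations uniformly (without replacement)
#' from the Cartesian product of the candidate sets, scores each with the
#' objective, and ranks ascending by score (lower is better, e.g. a
#' validation loss).
#'
#' @param space Named list of candidate vectors, one per parameter.
#' @param objective Function taking a named list (one value per parameter)
#'   and returning a numeric score.
#' @param budget Number of distinct configurations to evaluate; must not
#'   exceed the product of candidate-set sizes.
#' @param seed Integer seed for the draw.
#' @return A `data.frame` of evaluated configurations with a `score`
#'   column, ordered best first.
#' @examples
#' randomSearch(list(x = 1:5), function(cfg) (cfg$x - 3)^2,
#'              budget = 5, seed = 1)
#' @export
randomSearch <- function(space, objective, budget, seed) {
  if (length(space) == 0L || any(lengths(space) == 0L))
    stop("every parameter needs at least one candidate", call. = FALSE)
  sizes <- lengths(space)
  total <- prod(sizes)
  if (budget > total)
    stop(sprintf("budget %d exceeds the %d distinct configurations",
                 budget, total), call. = FALSE)
  draws <- .withSeed(seed, sample(total, budget))
  rows <- lapply(draws, function(d) {
    d <- d - 1L
    flat <- integer(length(sizes))
    for (j in seq_along(sizes)) {
      flat[j] <- d %% sizes[j] + 1L
      d <- d %/% sizes[j]
    }
    cfg <- .expandConfig(space, flat)
    c(cfg, list(score = objective(cfg)))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  df[order(df$score), , drop = FALSE]
}

#' Greedy coordinate-wise hyperparameter search
#'
#' Sweeps the parameters in their declared order, replacing each with its
#' best candidate while holding the others fixed, and repeats full sweeps
#' until one yields no improvement. The returned configuration is a local
#' optimum along coordinates and never scores worse than the start.
#'
#' @param space Named list of candidate vectors.
#' @param start Named list giving the starting value of every parameter
#'   (each must be among its candidates).
#' @param objective Scoring function as in [randomSearch] (lower is better).
#' @return A list with `config`, `score` and `evaluations` (objective call
#'   count).
#' @export
greedySearch <- function(space, start, objective) {
  if (!setequal(names(space), names(start)))
    stop("start must name exactly the parameters of the space", call. = FALSE)
  for (p in names(space))
    if (!(start[[p]] %in% space[[p]]))
      stop(sprintf("start value for '%s' is not among its candidates", p),
           call. = FALSE)
  cur <- start[names(space)]
  best <- objective(cur)
  evals <- 1L
  repeat {
    improved <- FALSE
    for (p in names(space)) {
      for (v in space[[p]]) {
        if (identical(v, cur[[p]])) next
        cand <- cur
        cand[[p]] <- v
        sc <- objective(cand)
        evals <- evals + 1L
        if (sc < best) {
          best <- sc
          cur <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(config = cur, score = best, evaluations = evals)
}

#' Classical regression harness
#'
#' Thin wrapper dispatching to established implementations of the five
#' classical regressors used as descriptor-based baselines: ridge
#' regression and elastic net (glmnet), a decision tree (rpart), a random
#' forest (randomForest) and a support vector machine (e1071). The harness
#' owns the protocol (feature scaling via [fitScaler], tuning via
#' [greedySearch], held-out scoring via [regressionMetrics]); the
#' algorithms themselves are delegated.
#'
#' @param xTrain,xTest Numeric feature matrices.
#' @param yTrain Numeric response for the training rows.
#' @param method One of `"ridge"`, `"elastic_net"`, `"tree"`,
#'   `"random_forest"`, `"svm"`.
#' @param ... Passed to the underlying fitting function.
#' @return Numeric vector of predictions for `xTest`.
#' @export
classicalRegression <- function(xTrain, yTrain, xTest,
                                method = c("ridge", "elastic_net", "tree",
                                           "random_forest", "svm"), ...) {
  method <- match.arg(method)
  xTrain <- as.matrix(xTrain)
  xTest <- as.matrix(xTest)
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE))
      stop(sprintf("package '%s' is required for method '%s'", pkg, method),
           call. = FALSE)
  }
  if (method %in% c("ridge", "elastic_net")) {
    need("glmnet")
    alpha <- if (method == "ridge") 0 else 0.5
    fit <- glmnet::cv.glmnet(xTrain, yTrain, alpha = alpha, nfolds = 5, ...)
    as.numeric(stats::predict(fit, xTest, s = "lambda.min"))
  } else if (method == "tree") {
    need("rpart")
    df <- data.frame(y = yTrain, xTrain)
    fit <- rpart::rpart(y ~ ., data = df, ...)
    as.numeric(stats::predict(fit, data.frame(xTest)))
  } else if (method == "random_forest") {
    need("randomForest")
    fit <- randomForest::randomForest(xTrain, yTrain, ...)
    as.numeric(stats::predict(fit, xTest))
  } else {
    need("e1071")
    fit <- e1071::svm(xTrain, yTrain, ...)
    as.numeric(stats::predict(fit, xTest))
  }
}

#' Write a metric report as JSON
#'
#' @param metrics A `MetricReport`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
writeMetricsJson <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
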