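#' Architecture configuration for the residual regressor
#'
#' Creates a validated [ModelConfig-class]. The defaults reproduce the
#' full-size network used for growth-temperature pretraining: input length
#' 2000, one residual block with 512 filters, kernel 5, valid max-pooling
#' with pool size and stride 50, one hidden dense layer of 128 units and a
#' single linear output, dropout 0.3. With these values the flatten layer
#' has width `512 * (floor((2000 - 50)/50) + 1) = 20480`.
#'
#' @param inputLength Maximum input length in residues.
#' @param nBlocks Number of residual blocks (1-3).
#' @param filters Convolution filter count.
#' @param kernelSize Convolution kernel length.
#' @param poolSize,poolStride Max-pool window and stride (valid padding).
#' @param denseSizes Hidden fully connected widths (the final width-1 linear
#'   output is implied).
#' @param dropout Dropout ratio in `[0, 1)`.
#' @param seed Weight-initialization seed.
#' @return A [ModelConfig-class].
#' @examples
#' flattenDim(modelConfig())
#' @export
modelConfig <- function(inputLength = 2000L, nBlocks = 1L, filters = 512L,
                        kernelSize = 5L, poolSize = 50L, poolStride = 50L,
                        denseSizes = 128L, dropout = 0.3, seed = 1L) {
  new("ModelConfig",
      inputLength = as.integer(inputLength), nBlocks = as.integer(nBlocks),
      filters = as.integer(filters), kernelSize = as.integer(kernelSize),
      poolSize = as.integer(poolSize), poolStride = as.integer(poolStride),
      denseSizes = as.integer(denseSizes), dropout = as.numeric(dropout),
      seed = as.integer(seed))
}

#' Training configuration
#'
#' @param learningRate Adam learning rate.
#' @param batchSize Minibatch size.
#' @param epochs Number of passes over the training data.
#' @param validationFraction Fraction of the training data held out for
#'   per-epoch validation loss (0 disables).
#' @param seed Seed governing shuffling, the validation split and dropout.
#' @param warmStart When `TRUE` (default) and the output group is
#'   trainable, the output bias is shifted once before the first epoch so
#'   that the initial mean prediction equals the mean training label; this
#'   spares the optimizer from slowly traversing the label offset (Adam
#'   steps are learning-rate bounded) without affecting the learned
#'   sequence dependence.
#' @return A list of class `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 1e-3, batchSize = 64L, epochs = 10L,
                        validationFraction = 0, seed = 1L, warmStart = TRUE) {
  stopifnot(learningRate > 0, batchSize >= 1, epochs >= 1,
            validationFraction >= 0, validationFraction < 1)
  structure(list(learningRate = learningRate, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 validationFraction = validationFraction,
                 seed = as.integer(seed), warmStart = isTRUE(warmStart)),
            class = "TrainConfig")
}

#' Width of the flatten-layer representation
#'
#' Closed-form width of the vector produced by the flatten stage:
#' `filters * (floor((inputLength - poolSize)/poolStride) + 1)`. This equals
#' the realized width of the built network's flatten output.
#'
#' @param x A [ModelConfig-class] or [ThermoNet-class].
#' @return Integer width.
#' @examples
#' flattenDim(modelConfig(inputLength = 128, filters = 16,
#'                        poolSize = 8, poolStride = 8))
#' @rdname flattenDim
#' @export
setMethod("flattenDim", "ModelConfig", function(x) {
  x@filters * ((x@inputLength - x@poolSize) %/% x@poolStride + 1L)
})

#' @rdname flattenDim
#' @export
setMethod("flattenDim", "ThermoNet", function(x) flattenDim(x@config))

.featureLayers <- function(cfg) {
  f <- cfg@filters
  k <- cfg@kernelSize
  layers <- list(
    .newConv(20L, f, k, "conv_entry"),
    .newBN(f, "conv_entry"),
    list(type = "relu")
  )
  for (i in seq_len(cfg@nBlocks)) {
    g <- paste0("block", i)
    layers[[length(layers) + 1L]] <- list(
      type = "resblock", group = g,
      conv1 = .newConv(f, f, k, g), bn1 = .newBN(f, g),
      conv2 = .newConv(f, f, k, g), bn2 = .newBN(f, g))
  }
  layers[[length(layers) + 1L]] <- list(type = "pool", p = cfg@poolSize,
                                        w = cfg@poolStride)
  layers[[length(layers) + 1L]] <- list(type = "flatten")
  layers
}

.headLayers <- function(cfg) {
  din <- flattenDim(cfg)
  layers <- list(list(type = "dropout", rate = cfg@dropout))
  for (i in seq_along(cfg@denseSizes)) {
    g <- paste0("dense", i)
    d <- cfg@denseSizes[i]
    layers <- c(layers, list(
      .newDense(din, d, g),
      .newBN(d, g),
      list(type = "relu"),
      list(type = "dropout", rate = cfg@dropout)))
    din <- d
  }
  layers[[length(layers) + 1L]] <- .newDense(din, 1L, "output")
  layers
}

.layerGroups <- function(layers)
  unique(unlist(lapply(layers, function(l) l$group)))

#' Build a residual convolutional regressor
#'
#' Constructs the network: one-hot input (`inputLength` x 20), entry
#' convolution (same padding) with batch normalization and ReLU, `nBlocks`
#' residual blocks (Conv-BN-ReLU-Conv-BN with identity skip, then ReLU),
#' valid max-pooling, flatten, then per hidden width dropout,
#' dense-BN-ReLU, and a final width-1 linear output. Weights use
#' Glorot-uniform initialization under the configuration seed. Weight
#' groups before the flatten stage are tagged `pre_flatten`, those after it
#' `post_flatten`; the tags drive the transfer-learning modes.
#'
#' @param config A [ModelConfig-class].
#' @return A [ThermoNet-class] with all groups trainable.
#' @examples
#' net <- buildThermoNet(modelConfig(inputLength = 120, filters = 4,
#'                                   poolSize = 10, poolStride = 10,
#'                                   denseSizes = 8, seed = 7))
#' weightGroups(net)
#' @export
buildThermoNet <- function(config) {
  validObject(config)
  feats <- NULL
  head <- NULL
  .withSeed(config@seed, {
    feats <- .featureLayers(config)
    head <- .headLayers(config)
  })
  groups <- c(.layerGroups(feats), .layerGroups(head))
  new("ThermoNet", config = config, features = feats, head = head,
      trainable = stats::setNames(rep(TRUE, length(groups)), groups),
      mode = "from_scratch")
}

setMethod("show", "ThermoNet", function(object) {
  cfg <- object@config
  cat(sprintf(
    "ThermoNet: input %d x 20, %d residual block(s) x %d filters (kernel %d)\n",
    cfg@inputLength, cfg@nBlocks, cfg@filters, cfg@kernelSize))
  cat(sprintf("  pool %d/%d -> flatten width %d; dense: %s -> 1; dropout %.2f\n",
              cfg@poolSize, cfg@poolStride, flattenDim(cfg),
              paste(cfg@denseSizes, collapse = ", "), cfg@dropout))
  wg <- weightGroups(object)
  cat(sprintf("  mode '%s'; trainable groups: %s\n", object@mode,
              paste(wg$group[wg$trainable], collapse = ", ")))
})

#' Weight-group summary of a model
#'
#' One row per named weight group with its tag (`pre_flatten` or
#' `post_flatten`), trainability and parameter count.
#'
#' @param model A [ThermoNet-class].
#' @return A `data.frame(group, tag, trainable, nParams)`.
#' @export
weightGroups <- function(model) {
  count <- function(layers, g) {
    sum(vapply(layers, function(l) {
      if (is.null(l$group) || l$group != g) return(0L)
      switch(l$type,
        conv = length(l$W) + length(l$b),
        dense = length(l$W) + length(l$b),
        bn = length(l$gamma) + length(l$beta),
        resblock = length(l$conv1$W) + length(l$conv1$b) +
          length(l$conv2$W) + length(l$conv2$b) +
          length(l$bn1$gamma) + length(l$bn1$beta) +
          length(l$bn2$gamma) + length(l$bn2$beta),
        0L)
    }, integer(1)))
  }
  fg <- .layerGroups(model@features)
  hg <- .layerGroups(model@head)
  data.frame(
    group = c(fg, hg),
    tag = c(rep("pre_flatten", length(fg)), rep("post_flatten", length(hg))),
    trainable = model@trainable[c(fg, hg)],
    nParams = c(vapply(fg, function(g) count(model@features, g), integer(1)),
                vapply(hg, function(g) count(model@head, g), integer(1))),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract model weights by group
#'
#' Returns the numeric weight arrays of each group (useful to verify that
#' frozen groups are bit-identical across fine-tuning).
#'
#' @param model A [ThermoNet-class].
#' @param groups Optional character vector restricting to some groups.
#' @return Named list: per group, a list of parameter arrays.
#' @export
modelWeights <- function(model, groups = NULL) {
  grab <- function(layers) {
    out <- list()
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (is.null(l$group)) next
      p <- switch(l$type,
        conv = list(W = l$W, b = l$b),
        dense = list(W = l$W, b = l$b),
        bn = list(gamma = l$gamma, beta = l$beta,
                  rmean = l$rmean, rvar = l$rvar),
        resblock = list(W1 = l$conv1$W, b1 = l$conv1$b,
                        g1 = l$bn1$gamma, be1 = l$bn1$beta,
                        rm1 = l$bn1$rmean, rv1 = l$bn1$rvar,
                        W2 = l$conv2$W, b2 = l$conv2$b,
                        g2 = l$bn2$gamma, be2 = l$bn2$beta,
                        rm2 = l$bn2$rmean, rv2 = l$bn2$rvar),
        NULL)
      if (is.null(p)) next
      names(p) <- paste0("L", i, ".", names(p))
      out[[l$group]] <- c(out[[l$group]], p)
    }
    out
  }
  res <- c(grab(model@features), grab(model@head))
  merged <- list()
  for (g in unique(names(res)))
    merged[[g]] <- do.call(c, unname(res[names(res) == g]))
  if (!is.null(groups)) merged <- merged[groups]
  merged
}

# ---- forward / backward over a layer stack ----

# Runs layers on X ((B*L) x C for feature stacks, B x D after flatten).
# batchStats is taken per BN layer: only when training and its group is
# trainable; frozen groups always use running statistics so their outputs
# (and hence extracted representations) are unchanged by fine-tuning.
.stackForward <- function(layers, X, B, L, training, trainable) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    res <- switch(l$type,
      conv = .convForward(X, l$W, l$b, l$k, B, L),
      bn = {
        r <- .bnForward(X, l, training && isTRUE(trainable[[l$group]]))
        layers[[i]] <- r$layer
        r
      },
      relu = .reluForward(X),
      dropout = .dropoutForward(X, l$rate, training),
      dense = .denseForward(X, l$W, l$b),
      pool = .poolForward(X, l$p, l$w, B, L),
      flatten = .flattenForward(X, B, L),
      resblock = {
        bs <- training && isTRUE(trainable[[l$group]])
        skip <- X
        c1 <- .convForward(X, l$conv1$W, l$conv1$b, l$conv1$k, B, L)
        b1 <- .bnForward(c1$out, l$bn1, bs)
        layers[[i]]$bn1 <- b1$layer
        r1 <- .reluForward(b1$out)
        c2 <- .convForward(r1$out, l$conv2$W, l$conv2$b, l$conv2$k, B, L)
        b2 <- .bnForward(c2$out, l$bn2, bs)
        layers[[i]]$bn2 <- b2$layer
        s <- b2$out + skip
        r2 <- .reluForward(s)
        list(out = r2$out,
             cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                          c2 = c2$cache, b2 = b2$cache, r2 = r2$cache))
      },
      stop("unknown layer type: ", l$type))
    caches[[i]] <- res$cache
    X <- res$out
    if (l$type == "pool") L <- .poolOutLen(L, l$p, l$w)
  }
  list(out = X, caches = caches, layers = layers, L = L)
}

.stackBackward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    ca <- caches[[i]]
    if (l$type == "conv") {
      r <- .convBackward(dY, l$W, ca)
      grads[[i]] <- list(W = r$dW, b = r$db)
      dY <- r$dX
    } else if (l$type == "bn") {
      r <- .bnBackward(dY, l, ca)
      grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
      dY <- r$dX
    } else if (l$type == "relu") {
      dY <- dY * ca
    } else if (l$type == "dropout") {
      if (!is.null(ca)) dY <- dY * ca
    } else if (l$type == "dense") {
      r <- .denseBackward(dY, l$W, ca)
      grads[[i]] <- list(W = r$dW, b = r$db)
      dY <- r$dX
    } else if (l$type == "pool") {
      dY <- .poolBackward(dY, ca)
    } else if (l$type == "flatten") {
      dY <- .flattenBackward(dY, ca)
    } else if (l$type == "resblock") {
      dr2 <- dY * ca$r2
      dskip <- dr2
      r2 <- .bnBackward(dr2, l$bn2, ca$b2)
      rc2 <- .convBackward(r2$dX, l$conv2$W, ca$c2)
      dr1 <- rc2$dX * ca$r1
      r1 <- .bnBackward(dr1, l$bn1, ca$b1)
      rc1 <- .convBackward(r1$dX, l$conv1$W, ca$c1)
      grads[[i]] <- list(conv1.W = rc1$dW, conv1.b = rc1$db,
                         bn1.gamma = r1$dgamma, bn1.beta = r1$dbeta,
                         conv2.W = rc2$dW, conv2.b = rc2$db,
                         bn2.gamma = r2$dgamma, bn2.beta = r2$dbeta)
      dY <- rc1$dX + dskip
    }
  }
  list(grads = grads, dX = dY)
}

# Adam update of all trainable parameters in a stack; keys are prefixed so
# feature and head stacks do not collide.
.applyGrads <- function(layers, grads, trainable, adam, lr, prefix) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(l$group) || !isTRUE(trainable[[l$group]])) next
    for (pn in names(g)) {
      key <- paste0(prefix, i, ".", pn)
      parts <- strsplit(pn, ".", fixed = TRUE)[[1]]
      cur <- if (length(parts) == 2L) layers[[i]][[parts[1]]][[parts[2]]]
             else layers[[i]][[pn]]
      st <- .adamStep(adam, key, cur, g[[pn]], lr)
      adam <- st$state
      if (length(parts) == 2L) layers[[i]][[parts[1]]][[parts[2]]] <- st$param
      else layers[[i]][[pn]] <- st$param
    }
  }
  list(layers = layers, adam = adam)
}

# Residue-index lists for fast batch encoding; errors name the record.
.seqIdxList <- function(seqs, ids, Lmax) {
  w <- nchar(seqs)
  if (any(w > Lmax)) {
    bad <- which(w > Lmax)[1]
    stop(sprintf("sequence '%s' (length %d) exceeds model input length %d",
                 ids[bad], w[bad], Lmax), call. = FALSE)
  }
  idx <- lapply(strsplit(seqs, ""), match, .AA20)
  bad <- which(vapply(idx, anyNA, logical(1)))
  if (length(bad))
    stop(sprintf("sequence '%s' contains a nonstandard residue", ids[bad[1]]),
         call. = FALSE)
  idx
}

.encodeFromIdx <- function(idxList, Lmax) {
  B <- length(idxList)
  X <- matrix(0, B * Lmax, 20L)
  for (b in seq_len(B)) {
    ii <- idxList[[b]]
    X[cbind((b - 1L) * Lmax + seq_along(ii), ii)] <- 1
  }
  X
}

.forwardInference <- function(model, X, B) {
  f <- .stackForward(model@features, X, B, model@config@inputLength,
                     training = FALSE, trainable = model@trainable)
  h <- .stackForward(model@head, f$out, B, f$L,
                     training = FALSE, trainable = model@trainable)
  list(rep = f$out, pred = as.numeric(h$out))
}

.predictIdx <- function(model, idxList, chunk = 256L) {
  n <- length(idxList)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    X <- .encodeFromIdx(idxList[s:e], model@config@inputLength)
    out[s:e] <- .forwardInference(model, X, e - s + 1L)$pred
  }
  out
}

.representIdx <- function(model, idxList, chunk = 256L) {
  n <- length(idxList)
  out <- matrix(0, n, flattenDim(model@config))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    X <- .encodeFromIdx(idxList[s:e], model@config@inputLength)
    f <- .stackForward(model@features, X, e - s + 1L,
                       model@config@inputLength,
                       training = FALSE, trainable = model@trainable)
    out[s:e, ] <- f$out
  }
  out
}

#' Train a model with Adam on mean-squared-error loss
#'
#' Minibatch Adam on MSE between predicted and observed temperatures. Only
#' weight groups whose trainability flag is `TRUE` (see [setTransferMode])
#' are updated; batch-normalization layers in frozen groups keep using (and
#' never update) their running statistics, so a frozen feature extractor is
#' bit-identical after training. When every pre-flatten group is frozen the
#' flatten-layer representations are computed once and only the dense head
#' is iterated, which makes fine-tuning with a frozen extractor fast.
#' Shuffling, the validation split and dropout are all governed by the
#' training seed, so runs with identical seeds are reproducible.
#'
#' @param model A [ThermoNet-class].
#' @param x A labeled [ProteinSet-class]; all sequences must fit
#'   `inputLength`.
#' @param tc A [trainConfig()].
#' @return A list of class `TrainResult` with elements `model` (the updated
#'   [ThermoNet-class]) and `history` (`data.frame(epoch, train_loss,
#'   val_loss)`; `val_loss` is `NA` when `validationFraction` is 0).
#' @export
trainThermoNet <- function(model, x, tc) {
  if (!is(x, "ProteinSet") || length(x) == 0L)
    stop("training data must be a non-empty labeled ProteinSet", call. = FALSE)
  y <- x@label
  if (anyNA(y)) stop("every training record must have a label", call. = FALSE)
  Lmax <- model@config@inputLength
  idxList <- .seqIdxList(.seqStrings(x), names(x), Lmax)
  n <- length(idxList)
  fg <- .layerGroups(model@features)
  featFrozen <- !any(model@trainable[fg])
  history <- data.frame(epoch = seq_len(tc$epochs),
                        train_loss = NA_real_, val_loss = NA_real_)
  .withSeed(tc$seed, {
    if (tc$validationFraction > 0 && n >= 2L) {
      nVal <- max(1L, floor(tc$validationFraction * n))
      valIdx <- sample.int(n, nVal)
      trIdx <- setdiff(seq_len(n), valIdx)
    } else {
      valIdx <- integer(0)
      trIdx <- seq_len(n)
    }
    if (length(trIdx) == 0L) stop("no training records left", call. = FALSE)
    reps <- NULL
    if (featFrozen) reps <- .representIdx(model, idxList)
    if (isTRUE(tc$warmStart) && isTRUE(model@trainable[["output"]])) {
      probe <- trIdx[seq_len(min(length(trIdx), 512L))]
      p0 <- .predictIdx(model, idxList[probe])
      iOut <- length(model@head)
      model@head[[iOut]]$b <- model@head[[iOut]]$b +
        (mean(y[trIdx]) - mean(p0))
    }
    adam <- .adamInit()
    for (ep in seq_len(tc$epochs)) {
      perm <- trIdx[sample.int(length(trIdx))]
      sse <- 0
      for (s in seq(1L, length(perm), by = tc$batchSize)) {
        e <- min(s + tc$batchSize - 1L, length(perm))
        bi <- perm[s:e]
        B <- length(bi)
        if (featFrozen) {
          H <- reps[bi, , drop = FALSE]
          hf <- .stackForward(model@head, H, B, NA, TRUE, model@trainable)
          pred <- as.numeric(hf$out)
          resid <- pred - y[bi]
          dOut <- matrix(2 * resid / B, ncol = 1L)
          hb <- .stackBackward(hf$layers, hf$caches, dOut)
          adam$t <- adam$t + 1L
          up <- .applyGrads(hf$layers, hb$grads, model@trainable, adam,
                            tc$learningRate, "h")
          model@head <- up$layers
          adam <- up$adam
        } else {
          X <- .encodeFromIdx(idxList[bi], Lmax)
          ff <- .stackForward(model@features, X, B, Lmax, TRUE, model@trainable)
          hf <- .stackForward(model@head, ff$out, B, ff$L, TRUE, model@trainable)
          pred <- as.numeric(hf$out)
          resid <- pred - y[bi]
          dOut <- matrix(2 * resid / B, ncol = 1L)
          hb <- .stackBackward(hf$layers, hf$caches, dOut)
          fb <- .stackBackward(ff$layers, ff$caches, hb$dX)
          adam$t <- adam$t + 1L
          up <- .applyGrads(hf$layers, hb$grads, model@trainable, adam,
                            tc$learningRate, "h")
          model@head <- up$layers
          adam <- up$adam
          up <- .applyGrads(ff$layers, fb$grads, model@trainable, adam,
                            tc$learningRate, "f")
          model@features <- up$layers
          adam <- up$adam
        }
        sse <- sse + sum(resid^2)
      }
      history$train_loss[ep] <- sse / length(perm)
      if (length(valIdx)) {
        vp <- .predictIdx(model, idxList[valIdx])
        history$val_loss[ep] <- mean((vp - y[valIdx])^2)
      }
    }
  })
  structure(list(model = model, history = history), class = "TrainResult")
}

#' @export
print.TrainResult <- function(x, ...) {
  h <- x$history
  cat(sprintf("TrainResult: %d epochs; final train MSE %.4f%s\n",
              nrow(h), h$train_loss[nrow(h)],
              if (!is.na(h$val_loss[nrow(h)]))
                sprintf(", val MSE %.4f", h$val_loss[nrow(h)]) else ""))
  invisible(x)
}

#' Write a training history as CSV
#'
#' @param fit A `TrainResult`.
#' @param path Output CSV path (columns epoch, train_loss, val_loss).
#' @return Invisibly, `path`.
#' @export
writeHistoryCsv <- function(fit, path) {
  utils::write.table(fit$history, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Set the transfer-learning mode of a model
#'
#' Configures which weight groups a subsequent [trainThermoNet()] call may
#' update:
#' \describe{
#'   \item{from_scratch}{all weights re-initialized (under `seed`, default
#'     the configuration seed) and trainable;}
#'   \item{frozen_all}{every group frozen - the pretrained model is used
#'     without any further tuning;}
#'   \item{frozen_cnn}{groups before the flatten stage frozen, dense head
#'     trainable;}
#'   \item{tune_all}{all weights preserved and trainable.}
#' }
#'
#' @param model A [ThermoNet-class].
#' @param mode One of `"from_scratch"`, `"frozen_all"`, `"frozen_cnn"`,
#'   `"tune_all"`.
#' @param seed Optional re-initialization seed for `from_scratch`.
#' @return The updated [ThermoNet-class].
#' @rdname setTransferMode
#' @export
setMethod("setTransferMode", "ThermoNet", function(model, mode, seed = NULL) {
  modes <- c("from_scratch", "frozen_all", "frozen_cnn", "tune_all")
  if (!is.character(mode) || length(mode) != 1L || !(mode %in% modes))
    stop("mode must be one of: ", paste(modes, collapse = ", "), call. = FALSE)
  groups <- names(model@trainable)
  fg <- .layerGroups(model@features)
  if (mode == "from_scratch") {
    cfg <- model@config
    if (!is.null(seed)) cfg@seed <- as.integer(seed)
    fresh <- buildThermoNet(cfg)
    fresh@mode <- "from_scratch"
    return(fresh)
  }
  model@trainable[] <- switch(mode,
    frozen_all = FALSE,
    frozen_cnn = !(groups %in% fg),
    tune_all = TRUE)
  model@mode <- mode
  model
})

#' Predict temperatures for protein records
#'
#' One predicted temperature per record; a pure function of the model
#' weights and the encoded input (inference mode: running batch-norm
#' statistics, no dropout), so duplicated records give identical values and
#' the output is invariant to record order.
#'
#' @param object A [ThermoNet-class].
#' @param newdata A [ProteinSet-class] or character vector of sequences.
#' @param ... Unused.
#' @return Named numeric vector of predicted temperatures (degrees Celsius).
#' @export
setMethod("predict", "ThermoNet", function(object, newdata, ...) {
  if (is(newdata, "ProteinSet")) {
    seqs <- .seqStrings(newdata)
    ids <- names(newdata)
  } else {
    seqs <- toupper(as.character(newdata))
    ids <- if (!is.null(names(newdata))) names(newdata)
           else paste0("seq", seq_along(seqs))
  }
  idxList <- .seqIdxList(seqs, ids, object@config@inputLength)
  stats::setNames(.predictIdx(object, idxList), ids)
})

#' Extract flatten-layer representations
#'
#' Runs the feature-extractor stage (everything before the flatten) in
#' inference mode and returns the flatten-layer activations, one row per
#' record, with `flattenDim(model)` columns. Under the default full-size
#' configuration these are 20,480-dimensional sequence representations.
#'
#' @param model A [ThermoNet-class].
#' @param x A [ProteinSet-class] or character vector of sequences.
#' @return Numeric matrix, rows named by record id.
#' @rdname extractRepresentation
#' @export
setMethod("extractRepresentation", "ThermoNet", function(model, x) {
  if (is(x, "ProteinSet")) {
    seqs <- .seqStrings(x)
    ids <- names(x)
  } else {
    seqs <- toupper(as.character(x))
    ids <- if (!is.null(names(x))) names(x) else paste0("seq", seq_along(seqs))
  }
  idxList <- .seqIdxList(seqs, ids, model@config@inputLength)
  out <- .representIdx(model, idxList)
  rownames(out) <- ids
  out
})

#' Save / load a model checkpoint
#'
#' The model state is serialized with `saveRDS` and the architecture
#' configuration is written alongside as a JSON sidecar (`<path>.json`).
#'
#' @param model A [ThermoNet-class].
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `saveThermoNet` invisibly returns `path`; `loadThermoNet`
#'   returns the [ThermoNet-class].
#' @name checkpoint
NULL

#' @rdname checkpoint
#' @export
saveThermoNet <- function(model, path) {
  saveRDS(model, path)
  cfg <- model@config
  jsonlite::write_json(list(
    inputLength = cfg@inputLength, nBlocks = cfg@nBlocks,
    filters = cfg@filters, kernelSize = cfg@kernelSize,
    poolSize = cfg@poolSize, poolStride = cfg@poolStride,
    denseSizes = cfg@denseSizes, dropout = cfg@dropout, seed = cfg@seed,
    flattenDim = flattenDim(cfg), mode = model@mode),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname checkpoint
#' @export
loadThermoNet <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "ThermoNet"))
  m
}
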