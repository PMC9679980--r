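# Shared fixtures: tiny architectures, handcrafted surrogate networks and
# small random sequences. Everything is generated in code at test time.

tinyConfig <- function(...) {
  args <- list(inputLength = 64L, nBlocks = 1L, filters = 8L,
               kernelSize = 5L, poolSize = 8L, poolStride = 8L,
               denseSizes = 16L, dropout = 0.1, seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(modelConfig, args)
}

randomSeqs <- function(n, len, seed = 1) {
  aa <- aminoAlphabet()
  ThermoCNN:::.withSeed(seed, {
    vapply(seq_len(n), function(i)
      paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
  })
}

# A network with handcrafted weights whose prediction is exactly
# base + scale * (number of `letter` residues in the input window), built by
# making the entry convolution a center-tap letter detector, the residual
# block an identity map, pooling a no-op (pool = stride = 1), batch norms
# identity affine maps, and the dense head a summation. Gives closed-form
# oracles for occlusion tests.
makeCountingNet <- function(letter = "W", base = 100, scale = 10,
                            Lmax = 64L) {
  cfg <- modelConfig(inputLength = Lmax, nBlocks = 1L, filters = 4L,
                     kernelSize = 5L, poolSize = 1L, poolStride = 1L,
                     denseSizes = 4L, dropout = 0, seed = 1L)
  net <- buildThermoNet(cfg)
  eps <- ThermoCNN:::.BN_EPS
  idBN <- function(l, C) {
    l$gamma <- rep(1, C); l$beta <- rep(0, C)
    l$rmean <- rep(0, C); l$rvar <- rep(1 - eps, C)
    l
  }
  aaIdx <- match(letter, aminoAlphabet())
  f <- net@features
  # entry conv: filter 1 fires iff `letter` sits at the window center
  f[[1]]$W[] <- 0; f[[1]]$b[] <- 0
  f[[1]]$W[(3L - 1L) * 20L + aaIdx, 1L] <- 1
  f[[2]] <- idBN(f[[2]], 4L)
  # residual block reduced to the identity: second conv contributes zero
  f[[4]]$conv1$W[] <- 0; f[[4]]$conv1$b[] <- 0
  f[[4]]$conv2$W[] <- 0; f[[4]]$conv2$b[] <- 0
  f[[4]]$bn1 <- idBN(f[[4]]$bn1, 4L)
  f[[4]]$bn2 <- idBN(f[[4]]$bn2, 4L)
  net@features <- f
  h <- net@head
  # dense1 unit 1 sums the letter-detector channel across positions
  h[[2]]$W[] <- 0; h[[2]]$b[] <- 0
  pos <- seq_len(Lmax)  # flatten is position-major within channel 1
  h[[2]]$W[pos, 1L] <- 1
  h[[3]] <- idBN(h[[3]], 4L)
  h[[6]]$W[] <- 0
  h[[6]]$W[1L, 1L] <- scale
  h[[6]]$b[] <- base
  net@head <- h
  net
}

# A network predicting the same nonzero constant for every input.
makeConstantNet <- function(value = 5, Lmax = 64L) {
  net <- makeCountingNet(Lmax = Lmax)
  i <- length(net@head)
  net@head[[i]]$W[] <- 0
  net@head[[i]]$b[] <- value
  net
}
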