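#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom stats predict rnorm runif sd cor var phyper t.test setNames
#'   complete.cases quantile median
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

#' The 20-letter standard amino-acid alphabet
#'
#' Fixed alphabetical ordering of the standard one-letter codes used for
#' one-hot encoding and all composition descriptors. The ordering is part of
#' the package contract so that encodings and feature vectors are
#' reproducible across sessions.
#'
#' @return A character vector of length 20.
#' @examples
#' aminoAlphabet()
#' @export
aminoAlphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.DSSP8 <- c("B", "E", "G", "H", "I", "S", "T", "-")

#' ProteinSet: sequences with optional labels and annotations
#'
#' Central container of the package: a set of protein sequences (stored as a
#' [Biostrings::AAStringSet]) with an optional numeric temperature label
#' (degrees Celsius), an optional per-residue secondary-structure string
#' (DSSP 8-letter codes), and optional domain intervals (1-based, inclusive)
#' per record.
#'
#' @slot sequences An `AAStringSet` holding the sequences; names are ids.
#' @slot label Numeric vector of temperatures (NA when absent), parallel to
#'   the sequences.
#' @slot ss Character vector of secondary-structure strings (NA when absent).
#' @slot domains List parallel to the sequences; each element is `NULL` or a
#'   `data.frame` with columns `name`, `start`, `end`.
#' @slot setName Single string naming the set.
#'
#' @exportClass ProteinSet
setClass("ProteinSet",
  representation(
    sequences = "AAStringSet",
    label = "numeric",
    ss = "character",
    domains = "list",
    setName = "character"
  )
)

setValidity("ProteinSet", function(object) {
  n <- length(object@sequences)
  msg <- character()
  if (length(object@label) != n) msg <- c(msg, "label length must match sequences")
  if (length(object@ss) != n) msg <- c(msg, "ss length must match sequences")
  if (length(object@domains) != n) msg <- c(msg, "domains length must match sequences")
  if (length(object@setName) != 1L) msg <- c(msg, "setName must be a single string")
  if (n > 0 && any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "sequences must be non-empty")
  w <- Biostrings::width(object@sequences)
  has_ss <- !is.na(object@ss)
  if (any(has_ss) && any(nchar(object@ss[has_ss]) != w[has_ss]))
    msg <- c(msg, "ss strings must have the same length as their sequences")
  for (i in seq_len(n)) {
    d <- object@domains[[i]]
    if (is.null(d)) next
    if (!is.data.frame(d) || !all(c("name", "start", "end") %in% names(d))) {
      msg <- c(msg, sprintf("domains[[%d]] must be a data.frame with name/start/end", i))
      next
    }
    if (nrow(d) > 0 && (any(d$start < 1L) || any(d$end > w[i]) || any(d$start > d$end)))
      msg <- c(msg, sprintf("domain intervals of record %d must satisfy 1 <= start <= end <= length", i))
  }
  if (length(msg)) msg else TRUE
})

#' ModelConfig: architecture parameterization of the residual regressor
#'
#' Houses the architecture symbols of the network: input length, number of
#' residual blocks, filter count, convolution kernel size, max-pool size and
#' stride, dense-layer widths, dropout ratio and the weight-initialization
#' seed. The flatten-layer width is fully determined by these values as
#' `filters * (floor((inputLength - poolSize)/poolStride) + 1)`.
#'
#' @slot inputLength Maximum sequence length accepted by the network (residues).
#' @slot nBlocks Number of residual blocks, between 1 and 3.
#' @slot filters Number of convolution filters (channels).
#' @slot kernelSize Convolution kernel length (residues).
#' @slot poolSize Max-pooling window (valid padding).
#' @slot poolStride Max-pooling stride.
#' @slot denseSizes Widths of the fully connected layers before the final
#'   single linear output.
#' @slot dropout Dropout ratio in `[0, 1)` applied after the flatten and the
#'   first dense layer.
#' @slot seed Integer seed for weight initialization.
#'
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(
    inputLength = "integer",
    nBlocks = "integer",
    filters = "integer",
    kernelSize = "integer",
    poolSize = "integer",
    poolStride = "integer",
    denseSizes = "integer",
    dropout = "numeric",
    seed = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@nBlocks < 1L || object@nBlocks > 3L)
    msg <- c(msg, "nBlocks must be in [1, 3]")
  if (object@poolSize > object@inputLength)
    msg <- c(msg, "poolSize must not exceed inputLength")
  if (object@inputLength < 1L || object@filters < 1L || object@kernelSize < 1L ||
      object@poolSize < 1L || object@poolStride < 1L)
    msg <- c(msg, "all architecture dimensions must be positive")
  if (length(object@denseSizes) < 1L || any(object@denseSizes < 1L))
    msg <- c(msg, "denseSizes must contain at least one positive width")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' ThermoNet: a residual convolutional thermal-trait regressor
#'
#' Model state: the architecture configuration, the named weight groups
#' (each tagged `pre_flatten` or `post_flatten`) and per-group trainability
#' flags used by the transfer-learning modes. Predictions are a pure
#' function of the weights and the encoded input.
#'
#' @slot config A [ModelConfig-class] object.
#' @slot features List of layers up to and including the flatten stage.
#' @slot head List of layers after the flatten stage.
#' @slot trainable Named logical vector, one entry per weight group.
#' @slot mode Transfer mode last applied (`"from_scratch"` initially).
#'
#' @exportClass ThermoNet
setClass("ThermoNet",
  representation(
    config = "ModelConfig",
    features = "list",
    head = "list",
    trainable = "logical",
    mode = "character"
  )
)

#' RelevanceProfile: per-residue occlusion relevance of one protein
#'
#' Output of the occlusion procedure for one sequence: per-residue relative
#' prediction changes, their within-profile z-scores, and the significance
#' mask (`|z| > zThreshold`, strict).
#'
#' @slot id Record identifier.
#' @slot scores Numeric vector of per-residue relevance scores.
#' @slot z Numeric vector of standardized scores.
#' @slot significant Logical mask of significant positions.
#' @slot width Occlusion window length used (residues).
#' @slot zThreshold Threshold on `|z|`.
#'
#' @exportClass RelevanceProfile
setClass("RelevanceProfile",
  representation(
    id = "character",
    scores = "numeric",
    z = "numeric",
    significant = "logical",
    width = "integer",
    zThreshold = "numeric"
  )
)

setValidity("RelevanceProfile", function(object) {
  msg <- character()
  n <- length(object@scores)
  if (length(object@z) != n || length(object@significant) != n)
    msg <- c(msg, "scores, z and significant must have equal length")
  if (length(msg)) msg else TRUE
})

#' DescriptorVector: named per-family classical sequence features
#'
#' Ordered per-family blocks of classical sequence descriptors for one
#' protein, totalling 5,494 values under the default parameterization.
#'
#' @slot blocks Named list of numeric vectors, one per descriptor family,
#'   in canonical family order.
#'
#' @exportClass DescriptorVector
setClass("DescriptorVector",
  representation(blocks = "list")
)
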