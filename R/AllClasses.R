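#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib macnext, .registration = TRUE
NULL

#' Architectural hyperparameters of a MACNeXt network
#'
#' Holds every quantity needed to build, trace and audit the network: input
#' geometry, stem widths, per-stage widths and block repeats, the grouped
#' convolution convention, and the class count. The reference configuration
#' (the constructor defaults) uses stem widths 48/96, stage widths
#' \code{c(96, 192, 384, 768)} with repeats \code{c(1, 1, 3, 1)}, two
#' channels per convolution group, a plain (ungrouped) 1x1 channel
#' expansion and a grouped 1x1 squeeze; under that convention the network
#' carries 4,436,808 learnable scalars (4.4 million) at 24 classes.
#'
#' @slot inputHeight,inputWidth,inputChannels input image geometry (pixels,
#'   pixels, channels).
#' @slot stemWidths integer vector of length 2; output widths of the two
#'   stem convolutions. The second entry must equal \code{stageWidths[1]}.
#' @slot stageWidths integer vector of per-stage channel widths; each stage
#'   doubles the previous one.
#' @slot stageRepeats integer vector, number of main blocks per stage.
#' @slot channelsPerGroup channels seen by each group of every grouped
#'   convolution; must divide every width it is applied to.
#' @slot expansionGrouped logical; whether the 1x1 expansion inside the main
#'   block is grouped. The reference convention is \code{FALSE}.
#' @slot squeezeGrouped logical; whether the 1x1 squeeze back to the block
#'   width is grouped. The reference convention is \code{TRUE}.
#' @slot numClasses number of output classes (>= 2).
#' @slot bnEpsilon batch-normalization variance floor.
#' @slot initSeed integer seed driving deterministic weight initialization.
#'
#' @seealso [macnextConfig()] for the validated constructor,
#'   [traceShapes()], [countParameters()], [buildModel()].
#' @export
setClass("MACNeXtConfig",
  representation(
    inputHeight = "integer",
    inputWidth = "integer",
    inputChannels = "integer",
    stemWidths = "integer",
    stageWidths = "integer",
    stageRepeats = "integer",
    channelsPerGroup = "integer",
    expansionGrouped = "logical",
    squeezeGrouped = "logical",
    numClasses = "integer",
    bnEpsilon = "numeric",
    initSeed = "integer"
  )
)

.validConfig <- function(object) {
  f <- object@stageWidths
  r <- object@stageRepeats
  cpg <- object@channelsPerGroup
  if (length(f) < 1L || length(f) != length(r)) {
    return("stageWidths and stageRepeats must have equal, positive length")
  }
  if (any(r < 1L)) return("stageRepeats must all be >= 1")
  if (length(object@stemWidths) != 2L) {
    return("stemWidths must hold exactly two widths")
  }
  if (object@stemWidths[2L] != f[1L]) {
    return("second stem width must equal the first stage width")
  }
  if (length(f) > 1L && any(f[-1L] != 2L * f[-length(f)])) {
    return("each stage width must double the previous one")
  }
  if (cpg < 1L) return("channelsPerGroup must be positive")
  widths <- c(object@stemWidths, f, 2L * f)
  if (any(widths %% cpg != 0L)) {
    return("channelsPerGroup must divide every stem and stage width")
  }
  if (object@squeezeGrouped && cpg %% 2L != 0L) {
    return(paste(
      "a grouped 2F->F squeeze requires an even channelsPerGroup",
      "(the group count of the 2F input must divide F)"
    ))
  }
  if (object@numClasses < 2L) return("numClasses must be at least 2")
  if (object@bnEpsilon <= 0) return("bnEpsilon must be positive")
  if (object@inputChannels < 1L) return("inputChannels must be positive")
  if (object@inputHeight < 4L || object@inputWidth < 4L) {
    return("input sides must be at least 4 pixels")
  }
  # spatial degeneracy: sides must stay >= 2 before the final stage
  side <- function(x) as.integer(ceiling(x / 2))
  h <- side(side(object@inputHeight))
  w <- side(side(object@inputWidth))
  nstage <- length(f)
  if (nstage > 1L) {
    for (s in seq_len(nstage - 1L)) {
      if (h < 2L || w < 2L) {
        return(sprintf(
          "spatial size collapses to %dx%d before the final stage", h, w
        ))
      }
      h <- side(h)
      w <- side(w)
    }
  }
  TRUE
}

setValidity("MACNeXtConfig", .validConfig)

#' A built MACNeXt network
#'
#' Created by [buildModel()]. The \code{layers} slot holds the nested layer
#' list (stem, stages with their blocks and downsampling layers, head);
#' every learnable array inside it was drawn deterministically from the
#' configuration's \code{initSeed}.
#'
#' @slot config the [MACNeXtConfig-class] the network was built from.
#' @slot layers nested named list of layer objects (internal layout).
#' @seealso [buildModel()], [predictProba()], [trainModel()],
#'   [saveCheckpoint()].
#' @export
setClass("MACNeXtModel",
  representation(config = "MACNeXtConfig", layers = "list")
)

#' Training protocol configuration
#'
#' Defaults follow the study protocol: a stratified 64/16/20
#' train/validation/test split obtained by two nested 80/20 splits, momentum
#' SGD (momentum 0.9) at a constant learning rate of 0.01, mini-batches of
#' 128, 30 epochs, and weight decay 1e-4 on convolution and fully connected
#' weights.
#'
#' @slot trainFraction,valFraction,testFraction partition fractions; must
#'   sum to 1.
#' @slot momentum momentum coefficient in `[0, 1)`.
#' @slot epochs number of training epochs.
#' @slot batchSize mini-batch size.
#' @slot learningRate constant learning rate.
#' @slot weightDecay L2 penalty applied to convolution and FC weights.
#' @slot balancedBatches logical; draw class-balanced mini-batches instead
#'   of a plain shuffle.
#' @slot seed integer seed for splitting, shuffling and batch composition.
#' @seealso [trainConfig()], [splitDataset()], [trainModel()].
#' @export
setClass("TrainConfig",
  representation(
    trainFraction = "numeric",
    valFraction = "numeric",
    testFraction = "numeric",
    momentum = "numeric",
    epochs = "integer",
    batchSize = "integer",
    learningRate = "numeric",
    weightDecay = "numeric",
    balancedBatches = "logical",
    seed = "integer"
  )
)

.validTrainConfig <- function(object) {
  fr <- c(object@trainFraction, object@valFraction, object@testFraction)
  if (any(fr <= 0)) return("all split fractions must be positive")
  if (abs(sum(fr) - 1) > 1e-8) return("split fractions must sum to 1")
  if (object@momentum < 0 || object@momentum >= 1) {
    return("momentum must lie in [0, 1)")
  }
  if (object@epochs < 1L) return("epochs must be at least 1")
  if (object@batchSize < 1L) return("batchSize must be at least 1")
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@weightDecay < 0) return("weightDecay must be nonnegative")
  TRUE
}

setValidity("TrainConfig", .validTrainConfig)
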