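# The three-block backbone family.
#
# A setting hp = {B, Opt, Lr, Mn, Epo} determines the whole network: each
# of the three blocks repeats (conv3x3 -> batchnorm -> relu) B times, with
# 2x2 stride-2 max-pooling after blocks 1 and 2, then global average
# pooling, a 2-unit fully connected layer and softmax.  The first block
# uses numKernal = 128 / sqrt(B) kernels (rounded half away from zero) and
# the count doubles in each subsequent block, so the final block carries
# 4 * numKernal feature maps.
#
# Two conventions deserve a note.  First, the kernel rule's "depth" is the
# per-block convolution count B, not the fixed block count 3: only that
# binding makes B = 2 give 91 -> 182 -> 364 final feature maps, the
# configuration the rest of the package (and its audit tooling) treats as
# the optimum.  Second, convolutions run with stride 1 and padding 1:
# stride-2 convolutions through up to 15 conv layers plus two pools from a
# 128-pixel input would collapse the spatial extent below 1x1, so spatial
# reduction is left to the pooling layers, giving a 32x32 map before
# global average pooling for every B at the 128-pixel input.

#' Construct a hyperparameter setting
#'
#' @param B block-repeat count (convolutional layers per block), 1-5.
#' @param Opt solver: `"adam"`, `"sgdm"` or `"rmsprop"`.
#' @param Lr L2-regularization coefficient in `[1e-10, 1e-2]`.
#' @param Mn mini-batch size: 32, 64 or 128.
#' @param Epo maximum epochs, 50-250.
#' @return a [HyperParams-class].
#' @export
hyperParams <- function(B, Opt, Lr, Mn, Epo) {
  methods::new("HyperParams", B = as.integer(B), Opt = Opt,
               Lr = as.numeric(Lr), Mn = as.integer(Mn),
               Epo = as.integer(Epo))
}

#' The reported optimal hyperparameter setting
#'
#' The setting selected by the Bayesian-optimisation search on the pooled
#' clinical training collections: `B = 2`, Adam, `Lr = 6.8012e-7`,
#' mini-batch 64, 50 epochs.  Building this setting yields the 6-conv-layer
#' network with 364 final-block feature maps.
#'
#' @return a [HyperParams-class].
#' @export
optimalHyperParams <- function() {
  hyperParams(B = 2L, Opt = "adam", Lr = 6.8012e-7, Mn = 64L, Epo = 50L)
}

#' First-block kernel count
#'
#' `numKernal = 128 / sqrt(B)`, rounded half away from zero.  The constant
#' 128 keeps the first block wide enough at the maximal depth; dividing by
#' `sqrt(B)` keeps the parameter budget roughly flat as B grows.
#'
#' @param B block-repeat count in `[1, 5]`.
#' @return integer kernel count of the first block.
#' @examples
#' kernelCount(1)  # 128
#' kernelCount(2)  # 91
#' @export
kernelCount <- function(B) {
  if (!is.numeric(B) || length(B) != 1L || B != as.integer(B) ||
      B < 1 || B > 5)
    stop("'B' must be an integer in [1, 5]")
  as.integer(roundHalfAway(128 / sqrt(B)))
}

#' Build the backbone architecture for a hyperparameter setting
#'
#' @param hp a [HyperParams-class].
#' @param inputSize spatial side of the square input (default 128); must
#'   be divisible by 4 so the two pooling stages land on whole pixels.
#' @param channels input channels (1 for grayscale; 3 replicates the
#'   grayscale plane for compatibility experiments).
#' @param baseKernels first-block kernel count; defaults to
#'   `kernelCount(hp@B)`.  Overriding it (e.g. to 8) gives a narrow
#'   desk-scale variant with the identical layer structure.
#' @return an [ArchitectureSpec-class].
#' @examples
#' spec <- buildArchitecture(optimalHyperParams())
#' nConvLayers(spec)        # 6
#' finalBlockKernels(spec)  # 364
#' @export
buildArchitecture <- function(hp, inputSize = 128L, channels = 1L,
                              baseKernels = NULL) {
  stopifnot(methods::is(hp, "HyperParams"))
  methods::validObject(hp)
  inputSize <- as.integer(inputSize)
  if (inputSize < 8L || inputSize %% 4L != 0L)
    stop("'inputSize' must be >= 8 and divisible by 4")
  k1 <- if (is.null(baseKernels)) kernelCount(hp@B) else as.integer(baseKernels)
  stopifnot(k1 >= 1L)
  blockKernels <- c(k1, 2L * k1, 4L * k1)

  layers <- list()
  inCh <- as.integer(channels)
  ci <- 0L
  for (blk in 1:3) {
    for (rep in seq_len(hp@B)) {
      ci <- ci + 1L
      layers <- c(layers, list(
        list(kind = "conv3x3", name = sprintf("conv_%d", ci),
             kernels = blockKernels[blk], inChannels = inCh,
             stride = 1L, padding = 1L),
        list(kind = "batchnorm", name = sprintf("bn_%d", ci),
             channels = blockKernels[blk]),
        list(kind = "relu", name = sprintf("relu_%d", ci))))
      inCh <- blockKernels[blk]
    }
    if (blk < 3)
      layers <- c(layers, list(
        list(kind = "maxpool2x2", name = sprintf("pool_%d", blk),
             stride = 2L)))
  }
  layers <- c(layers, list(
    list(kind = "gap", name = "gap"),
    list(kind = "fc", name = "fc", inFeatures = blockKernels[3],
         outFeatures = 2L),
    list(kind = "softmax", name = "softmax")))

  spec <- methods::new("ArchitectureSpec",
    layers = layers, inputSize = inputSize, channels = as.integer(channels),
    B = hp@B, baseKernels = k1,
    nConvLayers = 3L * hp@B, finalBlockKernels = blockKernels[3],
    nParameters = 0)
  spec@nParameters <- countParameters(spec)
  spec
}

#' Count learnable parameters of an architecture
#'
#' Sums convolution weights and biases (`3*3*in*out + out`), batchnorm
#' scale and shift (`2*channels`) and fully-connected weights and biases
#' (`in*out + out`).
#'
#' @param spec an [ArchitectureSpec-class].
#' @return total learnable parameter count (numeric, exact integer value).
#' @export
countParameters <- function(spec) {
  stopifnot(methods::is(spec, "ArchitectureSpec"))
  total <- 0
  for (ly in spec@layers) {
    total <- total + switch(ly$kind,
      conv3x3 = 9 * ly$inChannels * ly$kernels + ly$kernels,
      batchnorm = 2 * ly$channels,
      fc = ly$inFeatures * ly$outFeatures + ly$outFeatures,
      0)
  }
  total
}

#' Model complexity report
#'
#' One-row data frame with layer count, learnable-parameter count and a
#' serialized-size estimate (4 bytes per parameter, single precision).
#'
#' @param spec an [ArchitectureSpec-class].
#' @param model model name for the report row.
#' @return data.frame with columns `model`, `n_layers`, `n_parameters`,
#'   `size_estimate_bytes`.
#' @export
complexityReport <- function(spec, model = "backbone") {
  data.frame(model = model,
             n_layers = length(spec@layers),
             n_parameters = spec@nParameters,
             size_estimate_bytes = 4 * spec@nParameters,
             stringsAsFactors = FALSE)
}

#' Serialize / restore an architecture as JSON
#'
#' The JSON carries the layer list and the derived counts; reading it back
#' reproduces an identical [ArchitectureSpec-class].
#'
#' @param spec an [ArchitectureSpec-class].
#' @param path optional file path; when `NULL` the JSON string is
#'   returned.
#' @return `architectureToJson`: the JSON string (invisibly when written
#'   to a file); `architectureFromJson`: an [ArchitectureSpec-class].
#' @export
architectureToJson <- function(spec, path = NULL) {
  payload <- list(inputSize = spec@inputSize, channels = spec@channels,
                  B = spec@B, baseKernels = spec@baseKernels,
                  nConvLayers = spec@nConvLayers,
                  finalBlockKernels = spec@finalBlockKernels,
                  nParameters = spec@nParameters,
                  layers = spec@layers)
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' @rdname architectureToJson
#' @param json JSON string or file path produced by `architectureToJson`.
#' @export
architectureFromJson <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  toInt <- function(x) if (is.null(x)) x else as.integer(x)
  layers <- lapply(p$layers, function(ly) {
    for (f in c("kernels", "inChannels", "stride", "padding", "channels",
                "inFeatures", "outFeatures"))
      if (!is.null(ly[[f]])) ly[[f]] <- as.integer(ly[[f]])
    ly
  })
  methods::new("ArchitectureSpec",
    layers = layers, inputSize = toInt(p$inputSize),
    channels = toInt(p$channels), B = toInt(p$B),
    baseKernels = toInt(p$baseKernels), nConvLayers = toInt(p$nConvLayers),
    finalBlockKernels = toInt(p$finalBlockKernels),
    nParameters = as.numeric(p$nParameters))
}
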