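#' Pyramid-grouped convolution group schedule
#'
#' Chooses per-layer group counts transitioning from dense to sparse channel
#' connectivity: layer l of L gets the divisor of `channels` nearest to
#' `channels^((l-1)/(L-1))`, so the first layer is a standard convolution
#' (1 group) and the last is depth-wise (`channels` groups). Ties between two
#' equally near divisors resolve to the smaller (denser) one.
#'
#' @param nLayers number of convolution layers in the pyramid (>= 1).
#' @param channels channel count the groups must divide (>= 1).
#' @return integer vector of length `nLayers`, non-decreasing, each element a
#'   divisor of `channels`; `nLayers = 1` gives `c(1)`.
#' @examples
#' pgcGroupSchedule(3, 64) # 1, 8, 64
#' @export
pgcGroupSchedule <- function(nLayers, channels) {
  nLayers <- as.integer(nLayers)
  channels <- as.integer(channels)
  if (is.na(nLayers) || nLayers < 1L) stop("nLayers must be >= 1")
  if (is.na(channels) || channels < 1L) stop("channels must be >= 1")
  if (nLayers == 1L) return(1L)
  divs <- which(channels %% seq_len(channels) == 0L)
  targets <- channels^((seq_len(nLayers) - 1) / (nLayers - 1))
  vapply(targets, function(t) divs[which.min(abs(divs - t))], integer(1))
}

#' Grouped 2-D convolution
#'
#' Partitions input and output channels into `groups` contiguous blocks;
#' output channels of group i depend only on input channels of group i.
#' `groups = 1` is a standard convolution, `groups = Cin = Cout` is
#' depth-wise.
#'
#' @param x feature map, array `h x w x Cin`.
#' @param weights kernel array `kh x kw x (Cin/groups) x Cout`.
#' @param groups group count; must divide both channel counts.
#' @param stride,padding integer convolution geometry (zero padding).
#' @param bias optional numeric vector of length `Cout`.
#' @return feature map array `ho x wo x Cout`.
#' @export
groupedConv <- function(x, weights, groups = 1L, stride = 1L,
                        padding = dim(weights)[1L] %/% 2L, bias = NULL) {
  stopifnot(length(dim(x)) == 3L, length(dim(weights)) == 4L)
  d <- dim(weights)
  cin <- dim(x)[3L]
  if (cin %% groups != 0L || d[4L] %% groups != 0L ||
      cin %/% groups != d[3L])
    stop("groups must divide the input and output channel counts")
  conv2d_fwd(x, wAs3d(weights), as.integer(d),
             if (is.null(bias)) numeric(0) else bias,
             as.integer(stride), as.integer(padding), as.integer(groups))
}

#' Encode an image with the texture-biased stream
#'
#' Runs the pyramid-grouped-convolution backbone of `model` on one RGB image
#' and returns the final-stage feature map (spatial size divided by the
#' backbone's downsampling factor; 2048 channels for the 50-layer variant).
#'
#' @param model an [STNet-class].
#' @param image array `h x w x 3`, values typically in \[0, 1\].
#' @return feature map array.
#' @export
textureEncode <- function(model, image) {
  checkImageInput(image)
  nnForward(model@modules$textureEnc, image)$y
}
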