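#' Bilinear interpolation at a fractional position
#'
#' Samples a single channel at a real-valued (row, col) position, 0-based with
#' pixel centers at integers. The value is the bilinear blend of the four
#' surrounding grid points; reads outside the array contribute zero, matching
#' the zero-padding convention of the convolutions.
#'
#' @param x numeric matrix (one feature-map channel).
#' @param point numeric length-2 vector `(row, col)`, 0-based.
#' @return scalar sample value.
#' @examples
#' bilinearSample(matrix(0:3, 2, 2, byrow = TRUE), c(0.5, 0.5)) # 1.5
#' @export
bilinearSample <- function(x, point) {
  stopifnot(is.matrix(x), length(point) == 2L, all(is.finite(point)))
  bilinear_sample_cpp(x, point[1L], point[2L])
}

#' Deformable 2-D convolution
#'
#' Convolution whose kernel taps are displaced by a spatially varying offset
#' field: `y(p) = sum_k w(p_k) x(p + p_k + dp_k)`, fractional reads resolved
#' by bilinear interpolation. With an all-zero offset field this reduces
#' exactly to the standard convolution with the same weights.
#'
#' Tap index k runs over the kernel grid column-major (rows fastest);
#' offset channels `2k-1` and `2k` (1-based) hold the row and column
#' displacement of tap k in pixels.
#'
#' @param x feature map, array `h x w x Cin`.
#' @param weights kernel array `kh x kw x Cin x Cout`.
#' @param offsets array `ho x wo x 2N` with `N = kh*kw`; spatial size must
#'   match the output grid.
#' @param stride,padding convolution geometry.
#' @param bias optional length-`Cout` vector.
#' @return feature map array `ho x wo x Cout`.
#' @export
deformableConv <- function(x, weights, offsets, stride = 1L,
                           padding = dim(weights)[1L] %/% 2L, bias = NULL) {
  stopifnot(length(dim(x)) == 3L, length(dim(weights)) == 4L,
            length(dim(offsets)) == 3L)
  d <- dim(weights)
  if (dim(x)[3L] != d[3L]) stop("input channel count mismatch")
  if (dim(offsets)[3L] != 2L * d[1L] * d[2L])
    stop("offset field must carry 2 * kh * kw channels")
  dconv2d_fwd(x, wAs3d(weights), as.integer(d),
              if (is.null(bias)) numeric(0) else bias, offsets,
              as.integer(stride), as.integer(padding))
}

#' Encode an image with the shape-biased stream
#'
#' Runs the deformable-convolution encoder on one RGB image. The output has
#' the same spatial/channel geometry as [textureEncode()] so the two feature
#' maps can be concatenated. The offset-predicting layers are zero-initialized,
#' so a freshly built encoder behaves exactly like its non-deformable
#' counterpart.
#'
#' @inheritParams textureEncode
#' @return feature map array.
#' @export
shapeEncode <- function(model, image) {
  checkImageInput(image)
  nnForward(model@modules$shapeEnc, image)$y
}

#' Decode the lesion mask from the deepest shape feature
#'
#' Upsamples the shape encoder's final feature map back to input resolution
#' through transposed-convolution stages interleaved with residual blocks (no
#' shortcut connections from the encoder: all information passes through the
#' deepest feature map) and squashes the single-channel output to \[0, 1\].
#'
#' @param model an [STNet-class].
#' @param feature encoder output as returned by [shapeEncode()].
#' @return predicted mask, matrix `H x W` with values in (0, 1).
#' @export
shapeDecode <- function(model, feature) {
  stopifnot(length(dim(feature)) == 3L)
  geom <- model@modules$decoderInGeom
  if (!is.null(geom) && dim(feature)[3L] != geom)
    stop("feature channel count does not match the decoder input")
  out <- nnForward(model@modules$decoder, feature)$y
  matrix(out, dim(out)[1L], dim(out)[2L])
}

checkImageInput <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be an h x w x 3 array")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  invisible(TRUE)
}
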