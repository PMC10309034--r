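#' Global dual pooling of a feature map
#'
#' Collapses each channel to a scalar descriptor
#' `g_k = (mean_ij z_ijk + max_ij z_ijk) / 2`, balancing average and peak
#' characterization before channel attention.
#'
#' @param Z feature map array `h x w x c`, `h, w >= 1`.
#' @return numeric vector of length `c`.
#' @export
globalDualPool <- function(Z) {
  if (length(dim(Z)) != 3L || any(dim(Z)[1:2] < 1L) || length(Z) == 0L)
    stop("Z must be a non-empty h x w x c array")
  d <- dim(Z)
  Zm <- matrix(Z, d[1L] * d[2L], d[3L])
  0.5 * (colMeans(Zm) + apply(Zm, 2L, max))
}

#' Channel-attention weights from a pooled descriptor
#'
#' Two 1x1 transforms with logistic activations on both:
#' `w_att = sigma(W2' sigma(W1' g + b1) + b2)`. Every weight is strictly in
#' (0, 1), so applying them can only shrink feature magnitudes.
#'
#' @param g pooled descriptor, length `c` (see [globalDualPool()]).
#' @param w1 matrix `c x hidden` (hidden = `c / reduction`).
#' @param w2 matrix `hidden x c`.
#' @param b1,b2 optional bias vectors (default zero).
#' @return attention weights, length `c`, each in (0, 1).
#' @export
channelAttention <- function(g, w1, w2, b1 = NULL, b2 = NULL) {
  if (nrow(w1) != length(g)) stop("w1 must have one row per channel")
  if (ncol(w1) != nrow(w2)) stop("hidden dimensions of w1 and w2 disagree")
  if (ncol(w2) != length(g)) stop("w2 must map back to the channel count")
  if (is.null(b1)) b1 <- numeric(ncol(w1))
  if (is.null(b2)) b2 <- numeric(ncol(w2))
  h1 <- sigmoidFn(drop(crossprod(w1, g)) + b1)
  sigmoidFn(drop(crossprod(w2, h1)) + b2)
}

#' Weight a feature map channel by channel
#'
#' `Z'[i,j,k] = wAtt[k] * Z[i,j,k]`.
#'
#' @param Z feature map array `h x w x c`.
#' @param wAtt numeric vector of length `c`.
#' @return weighted feature map, same shape as `Z`.
#' @export
applyAttention <- function(Z, wAtt) {
  if (length(dim(Z)) != 3L || dim(Z)[3L] != length(wAtt))
    stop("attention weight count must match the channel count")
  sweep(Z, 3L, wAtt, "*")
}

#' Gradient-scaling layer (forward pass)
#'
#' Identity in the forward direction. During training the layer multiplies
#' every gradient flowing backward through it by `factor`; this is how the
#' classification-loss weight on the shape encoder (the alpha of the joint
#' objective) is realized. The backward contract is exercised through the
#' training engine; this function performs the forward part and validates
#' the factor.
#'
#' @param x feature map array.
#' @param factor positive scalar gradient multiplier.
#' @return `x`, unchanged.
#' @export
gradientScale <- function(x, factor) {
  nnGScale(factor) # validates
  x
}

## ---- internal CAFF module -------------------------------------------------

nnCAFF <- function(c, reduction = 16L) {
  hid <- max(1L, c %/% as.integer(reduction))
  list(kind = "caff",
       params = list(
         w1 = matrix(stats::rnorm(c * hid, 0, sqrt(2 / c)), c, hid),
         b1 = numeric(hid),
         w2 = matrix(stats::rnorm(hid * c, 0, sqrt(2 / hid)), hid, c),
         b2 = numeric(c)))
}

# attnMask is an inference-time ablation switch: channels with a 0 entry are
# removed from the fusion entirely -- excluded from the pooled descriptor the
# attention is computed from, and zeroed in the output.
caffForward <- function(m, Z, attnMask = NULL) {
  d <- dim(Z)
  n <- d[1L] * d[2L]
  Zm <- matrix(Z, n, d[3L])
  if (!is.null(attnMask)) Zm <- sweep(Zm, 2L, attnMask, "*")
  mx <- apply(Zm, 2L, max)
  amax <- apply(Zm, 2L, which.max)
  g <- 0.5 * (colMeans(Zm) + mx)
  u1 <- drop(crossprod(m$params$w1, g)) + m$params$b1
  h1 <- sigmoidFn(u1)
  u2 <- drop(crossprod(m$params$w2, h1)) + m$params$b2
  watt <- sigmoidFn(u2)
  Zp <- sweep(Zm, 2L, watt, "*")
  list(y = array(Zp, d),
       cache = list(Zm = Zm, g = g, h1 = h1, watt = watt,
                    amax = amax, d = d, attnMask = attnMask))
}

caffBackward <- function(m, cache, gy) {
  d <- cache$d
  n <- d[1L] * d[2L]
  Gm <- matrix(gy, n, d[3L])
  dwatt <- colSums(Gm * cache$Zm)
  gZ <- sweep(Gm, 2L, cache$watt, "*")
  du2 <- dwatt * cache$watt * (1 - cache$watt)
  dh1 <- drop(m$params$w2 %*% du2)
  du1 <- dh1 * cache$h1 * (1 - cache$h1)
  dg <- drop(m$params$w1 %*% du1)
  # pooling backward: mean spreads, max routes to the (first) argmax
  gZ <- gZ + matrix(rep(dg * (0.5 / n), each = n), n, d[3L])
  idx <- cbind(cache$amax, seq_len(d[3L]))
  gZ[idx] <- gZ[idx] + 0.5 * dg
  if (!is.null(cache$attnMask)) gZ <- sweep(gZ, 2L, cache$attnMask, "*")
  list(gx = array(gZ, d),
       grads = list(w1 = outer(cache$g, du1), b1 = du1,
                    w2 = outer(cache$h1, du2), b2 = du2))
}

## ---- fusion head ----------------------------------------------------------

nnFusion <- function(cTex, cShape, reduction = 16L, gradScale = 0.1,
                     caffEnabled = TRUE) {
  c <- cTex + cShape
  list(kind = "fusion",
       gscale = nnGScale(gradScale),
       caff = if (caffEnabled) nnCAFF(c, reduction) else NULL,
       fc = nnDense(c, 1L, wsd = sqrt(1 / c)),
       cTex = cTex, cShape = cShape, attnMask = NULL)
}

fusionForward <- function(fus, tex, shp) {
  dt <- dim(tex); ds <- dim(shp)
  if (any(dt[1:2] != ds[1:2]))
    stop("texture and shape feature maps must share spatial geometry")
  Z <- array(c(tex, shp), c(dt[1L], dt[2L], dt[3L] + ds[3L]))
  if (!is.null(fus$caff)) {
    rc <- caffForward(fus$caff, Z, fus$attnMask)
    Zp <- rc$y
    cacheC <- rc$cache
  } else {
    Zp <- Z
    cacheC <- NULL
  }
  d <- dim(Zp)
  n <- d[1L] * d[2L]
  pooled <- colMeans(matrix(Zp, n, d[3L]))
  logit <- sum(fus$fc$params$w[, 1L] * pooled) + fus$fc$params$b
  p <- sigmoidFn(logit)
  list(p = as.numeric(p),
       cache = list(caff = cacheC, pooled = pooled, p = as.numeric(p),
                    d = d, cTex = dt[3L], cShape = ds[3L]))
}

fusionBackward <- function(fus, cache, dLdp) {
  dlogit <- dLdp * cache$p * (1 - cache$p)
  gfc <- list(w = matrix(cache$pooled * dlogit, ncol = 1L), b = dlogit)
  d <- cache$d
  n <- d[1L] * d[2L]
  gpooled <- fus$fc$params$w[, 1L] * dlogit
  gZp <- array(rep(gpooled / n, each = n), d)
  if (!is.null(fus$caff)) {
    rc <- caffBackward(fus$caff, cache$caff, gZp)
    gZ <- rc$gx
    gcaff <- rc$grads
  } else {
    gZ <- gZp
    gcaff <- NULL
  }
  gtex <- gZ[, , seq_len(cache$cTex), drop = FALSE]
  gshp <- gZ[, , cache$cTex + seq_len(cache$cShape), drop = FALSE] *
    fus$gscale$factor
  list(gtex = gtex, gshp = gshp, grads = list(caff = gcaff, fc = gfc))
}

flattenFusionParams <- function(fus) {
  out <- list()
  if (!is.null(fus$caff))
    out <- c(out, flattenParams(fus$caff, "caff."))
  c(out, flattenParams(fus$fc, "fc."))
}

flattenFusionGrads <- function(fus, g) {
  out <- list()
  if (!is.null(fus$caff))
    out <- c(out, flattenGrads(fus$caff, g$caff, "caff."))
  c(out, flattenGrads(fus$fc, g$fc, "fc."))
}

unflattenFusionParams <- function(fus, flat) {
  if (!is.null(fus$caff))
    fus$caff <- unflattenParams(fus$caff, flat, "caff.")
  fus$fc <- unflattenParams(fus$fc, flat, "fc.")
  fus
}

#' Fuse texture and shape features and classify
#'
#' The shape feature map passes the gradient-scaling layer (identity
#' forward), the two maps are concatenated along channels, channel attention
#' re-weights the concatenated map (when enabled), and a global-average-pooled
#' descriptor feeds one fully connected layer with logistic output. A
#' probability strictly above 0.5 predicts the positive (malignant) class.
#'
#' @param textureFeat,shapeFeat feature maps `h x w x c_t` / `h x w x c_s`
#'   with matching spatial geometry.
#' @param params list with elements `w1`, `b1`, `w2`, `b2` (channel
#'   attention; omit or set `caffEnabled = FALSE` to fuse without
#'   attention), `fcW` (length `c_t + c_s`), `fcB` (scalar), `gradScale`
#'   (positive scalar, default 0.1), and optional `attnMask`, a 0/1 vector
#'   over the concatenated channels: channels masked to 0 are removed from
#'   the fusion -- excluded from the attention computation and zeroed in the
#'   output (ablation hook).
#' @return predicted probability, a scalar in (0, 1).
#' @export
fuseAndClassify <- function(textureFeat, shapeFeat, params) {
  cTex <- dim(textureFeat)[3L]
  cShape <- dim(shapeFeat)[3L]
  c <- cTex + cShape
  caffEnabled <- params$caffEnabled %||% !is.null(params$w1)
  fus <- list(kind = "fusion",
              gscale = nnGScale(params$gradScale %||% 0.1),
              caff = if (caffEnabled)
                list(kind = "caff",
                     params = list(w1 = params$w1, b1 = params$b1 %||% numeric(ncol(params$w1)),
                                   w2 = params$w2, b2 = params$b2 %||% numeric(c)))
              else NULL,
              fc = list(kind = "dense",
                        params = list(w = matrix(params$fcW, ncol = 1L),
                                      b = params$fcB %||% 0)),
              attnMask = params$attnMask)
  fusionForward(fus, textureFeat, shapeFeat)$p
}
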