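## Classification and shape losses. Natural log throughout; predicted
## probabilities are clamped to [eps, 1 - eps] with eps = 1e-7 so every loss
## stays finite.

.pEps <- 1e-7

clampP <- function(p) pmin(pmax(p, .pEps), 1 - .pEps)

#' Binary cross-entropy loss
#'
#' `-y log(p) - (1 - y) log(1 - p)` with natural logarithm; `p` is clamped
#' at 1e-7 from both ends.
#'
#' @param y labels in `{0, 1}` (vectorized).
#' @param p predicted probabilities in (0, 1).
#' @param reduce `"mean"` (batch mean, default) or `"none"` (per sample).
#' @return loss value(s), non-negative.
#' @export
crossEntropy <- function(y, p, reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  stopifnot(all(y %in% c(0, 1)), length(y) == length(p))
  pc <- clampP(p)
  l <- -y * log(pc) - (1 - y) * log(1 - pc)
  if (reduce == "mean") mean(l) else l
}

#' Asymmetric-loss parameter set
#'
#' `gammaPlus` and `gammaMinus` are the exponential focusing factors for the
#' positive and negative branches; `phi` is the probability cutoff of the
#' probability transfer `p_t = max(p - phi, 0)`. With many more negatives
#' than positives one sets `gammaPlus < gammaMinus` so negative-sample
#' gradients are damped harder; the constructor warns (without failing, so
#' sensitivity sweeps can explore the full grid) when that ordering is
#' violated.
#'
#' @param gammaPlus,gammaMinus focusing exponents, `>= 0`.
#' @param phi probability cutoff in `[0, 1)`.
#' @return a validated parameter list of class `"AsymLossParams"`.
#' @export
asymLossParams <- function(gammaPlus = 1, gammaMinus = 3, phi = 0.05) {
  stopifnot(gammaPlus >= 0, gammaMinus >= 0, phi >= 0, phi < 1)
  if (gammaPlus > gammaMinus)
    warning("gammaPlus > gammaMinus: negatives are damped less than positives")
  structure(list(gammaPlus = gammaPlus, gammaMinus = gammaMinus, phi = phi),
            class = "AsymLossParams")
}

#' Probability transfer
#'
#' `p_t = max(p - phi, 0)`: negatives predicted below the cutoff `phi`
#' contribute no loss (easy negatives are discarded).
#'
#' @param p probabilities in `[0, 1]` (vectorized).
#' @param phi cutoff in `[0, 1)`.
#' @return transferred probabilities.
#' @export
transferProbability <- function(p, phi) {
  stopifnot(phi >= 0, phi < 1)
  pmax(p - phi, 0)
}

#' Asymmetric classification loss
#'
#' Per sample: `-y (1-p)^gammaPlus log(p) - (1-y) p_t^gammaMinus log(1-p)`
#' with `p_t = max(p - phi, 0)` and the convention `0^0 = 1`, so
#' `gammaPlus = gammaMinus = 0, phi = 0` reduces exactly to [crossEntropy()].
#' For a negative sample with `p <= phi` the loss is exactly zero (when
#' `gammaMinus > 0`).
#'
#' @inheritParams crossEntropy
#' @param params an [asymLossParams()] list.
#' @return loss value(s), non-negative.
#' @export
asymmetricLoss <- function(y, p, params = asymLossParams(),
                           reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  stopifnot(all(y %in% c(0, 1)), length(y) == length(p))
  pc <- clampP(p)
  pt <- transferProbability(pc, params$phi)
  l <- -y * (1 - pc)^params$gammaPlus * log(pc) -
    (1 - y) * pt^params$gammaMinus * log(1 - pc)
  if (reduce == "mean") mean(l) else l
}

## d loss / d p, per sample (used by the trainer; clamp region treated as
## constant). For gammaMinus = 0 the focusing factor is the constant 1.
asymmetricLossGrad <- function(y, p, params) {
  pc <- clampP(p)
  gp <- params$gammaPlus
  gm <- params$gammaMinus
  pt <- pmax(pc - params$phi, 0)
  gpos <- gp * (1 - pc)^(pmax(gp - 1, 0)) * log(pc) - (1 - pc)^gp / pc
  if (gp == 0) gpos <- -1 / pc
  if (gm == 0) {
    gneg <- 1 / (1 - pc)
  } else {
    gneg <- ifelse(pt > 0,
                   -gm * pt^(gm - 1) * log(1 - pc) + pt^gm / (1 - pc),
                   0)
  }
  y * gpos + (1 - y) * gneg
}

crossEntropyGrad <- function(y, p) {
  pc <- clampP(p)
  -y / pc + (1 - y) / (1 - pc)
}

#' Shape (mask reconstruction) loss
#'
#' Pixel-wise mean squared error between the predicted mask and the ground
#' truth mask.
#'
#' @param pred predicted mask, values in `[0, 1]`.
#' @param mask ground-truth binary mask, same spatial size.
#' @return scalar loss, `>= 0`.
#' @export
shapeLoss <- function(pred, mask) {
  if (!all(dim(pred) == dim(mask)))
    stop("predicted and ground-truth masks must share spatial size")
  mean((pred - mask)^2)
}

#' Joint-objective loss weights
#'
#' `alpha` scales the classification loss reaching the shape encoder
#' (realized by the gradient-scaling layer); `beta` scales the shape loss.
#'
#' @param alpha,beta non-negative scalars, not both zero.
#' @return a validated list of class `"JointLossWeights"`.
#' @export
jointLossWeights <- function(alpha = 0.1, beta = 1) {
  stopifnot(alpha >= 0, beta >= 0)
  if (alpha == 0 && beta == 0) stop("alpha and beta cannot both be zero")
  structure(list(alpha = alpha, beta = beta), class = "JointLossWeights")
}

#' Per-parameter-group objectives of the joint training
#'
#' Maps the two per-sample losses onto the three parameter groups: the
#' texture encoder minimizes the classification loss alone; the shape decoder
#' minimizes the (beta-weighted) shape loss alone; the shape encoder
#' minimizes `alpha * L_CLS + beta * L_SHP`. For samples without a mask the
#' shape term is zero, so the decoder receives no gradient from them.
#'
#' @param lossCls classification loss (scalar).
#' @param lossShp shape loss (scalar; ignored when `maskAvailable` is FALSE).
#' @param weights a [jointLossWeights()] list.
#' @param maskAvailable does this sample carry a ground-truth mask?
#' @return list with `texturePath`, `shapeEncoderPath`, `decoderPath`.
#' @export
jointObjective <- function(lossCls, lossShp, weights = jointLossWeights(),
                           maskAvailable = TRUE) {
  stopifnot(is.finite(lossCls), is.finite(lossShp) || !maskAvailable)
  shp <- if (maskAvailable) weights$beta * lossShp else 0
  list(texturePath = lossCls,
       shapeEncoderPath = weights$alpha * lossCls + shp,
       decoderPath = shp)
}
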