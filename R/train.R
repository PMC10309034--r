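## Data loading, augmentation, the RMSprop optimizer and the joint training
## loop.

#' Load an image (PNG/JPEG-decoded PNG) as an h x w x 3 array
#'
#' Grayscale images are replicated to three channels, an alpha channel is
#' dropped, and the image is bilinearly resized to `size` when given.
#'
#' @param path PNG file path.
#' @param size optional square output size.
#' @return array `h x w x 3`, values in \[0, 1\].
#' @export
loadImage <- function(path, size = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3L] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  if (!is.null(size) && any(dim(img)[1:2] != size)) img <- resizeArray(img, size)
  img
}

#' Load a mask PNG as a binary matrix
#'
#' Grayscale values above 127/255 are foreground; after an optional resize
#' the mask is re-binarized at 0.5.
#'
#' @inheritParams loadImage
#' @return matrix with values in `{0, 1}`.
#' @export
loadMask <- function(path, size = NULL) {
  msk <- png::readPNG(path)
  if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
  msk <- (msk > 127 / 255) * 1
  if (!is.null(size) && any(dim(msk) != size)) {
    msk <- resizeArray(array(msk, c(dim(msk), 1L)), size)[, , 1L]
    msk <- (msk > 0.5) * 1
  }
  msk
}

resizeArray <- function(x, size) {
  d <- dim(x)
  warp_affine(x, size, size,
              (d[1L] - 1) / (size - 1), 0, 0,
              0, (d[2L] - 1) / (size - 1), 0, 0)
}

## Random rotation (uniform +/- 30 degrees) then random crop to 87.5% of the
## side, resized back; the identical geometric transform is applied to the
## mask, which is re-binarized afterwards. Draws from the current RNG stream.
augmentSample <- function(image, mask = NULL, rotDeg = 30, cropFrac = 0.875) {
  s <- dim(image)[1L]
  th <- stats::runif(1, -rotDeg, rotDeg) * pi / 180
  ct <- (s - 1) / 2
  a11 <- cos(th); a12 <- -sin(th); a21 <- sin(th); a22 <- cos(th)
  tr <- ct - (a11 * ct + a12 * ct)
  tc <- ct - (a21 * ct + a22 * ct)
  fill <- mean(image)
  image <- warp_affine(image, s, s, a11, a12, tr, a21, a22, tc, fill)
  if (!is.null(mask))
    mask <- warp_affine(array(mask, c(s, s, 1L)), s, s,
                        a11, a12, tr, a21, a22, tc, 0)[, , 1L]
  win <- max(2L, round(cropFrac * s))
  r0 <- sample.int(s - win + 1L, 1L) - 1L
  c0 <- sample.int(s - win + 1L, 1L) - 1L
  sc <- (win - 1) / (s - 1)
  image <- warp_affine(image, s, s, sc, 0, r0, 0, sc, c0, fill)
  if (!is.null(mask)) {
    mask <- warp_affine(array(mask, c(s, s, 1L)), s, s,
                        sc, 0, r0, 0, sc, c0, 0)[, , 1L]
    mask <- (mask > 0.5) * 1
  }
  list(image = image, mask = mask)
}

rmspropInit <- function(flat) list(sq = zeroLike(flat), buf = zeroLike(flat))

rmspropStep <- function(state, params, grads, lr, wd, momentum, alpha,
                        eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (wd > 0) g <- g + wd * params[[nm]]
    state$sq[[nm]] <- alpha * state$sq[[nm]] + (1 - alpha) * g * g
    state$buf[[nm]] <- momentum * state$buf[[nm]] +
      g / (sqrt(state$sq[[nm]]) + eps)
    params[[nm]] <- params[[nm]] - lr * state$buf[[nm]]
  }
  list(state = state, params = params)
}

#' Train a two-stream model on a manifest
#'
#' Joint optimization: per batch the classification loss (asymmetric or
#' cross-entropy, per config) backpropagates into the fusion head, the
#' texture encoder, and -- damped by the gradient-scaling factor alpha --
#' the shape encoder; the beta-weighted mask L2 loss backpropagates through
#' the decoder into the shape encoder for the samples that carry a mask.
#' Optimizer is RMSprop with momentum. The run is fully seeded
#' (shuffling, augmentation) from `config$train$seed`. When the manifest has
#' a non-empty `val` split, the parameters with the best validation F1 are
#' restored into the model at the end.
#'
#' @param model an [STNet-class] (updated in place).
#' @param manifest a [LesionManifest-class]; rows tagged `train` are used
#'   (all rows when no tags are set).
#' @param verbose print per-epoch progress.
#' @return list with `model`, `history` (data.frame of per-step `step`,
#'   `lossCls`, `lossShp`, `lr`) and `valF1` (best validation F1, `NA`
#'   without a val split).
#' @export
trainModel <- function(model, manifest, verbose = FALSE) {
  cfg <- model@config
  tr <- cfg$train
  md <- manifestData(manifest)
  rows <- if (any(nzchar(md$split))) md[md$split == "train", ] else md
  if (!nrow(rows) || length(unique(rows$label)) < 2L)
    stop("training needs at least one sample of each class")
  valRows <- md[md$split == "val", ]
  beta <- cfg$loss$beta

  cache <- lapply(seq_len(nrow(rows)), function(i) {
    img <- loadImage(rows$.image[i], tr$imageSize)
    msk <- if (nzchar(rows$.mask[i])) loadMask(rows$.mask[i], tr$imageSize)
    list(image = img, mask = msk, label = rows$label[i])
  })

  params <- modelParams(model)
  state <- rmspropInit(params)
  hist <- list()
  step <- 0L
  bestF1 <- NA_real_
  bestParams <- NULL

  withSeed(tr$seed, {
    for (epoch in seq_len(tr$epochs)) {
      ord <- sample.int(nrow(rows))
      bstarts <- seq(1L, length(ord), by = tr$batchSize)
      for (bs in bstarts) {
        if (step >= tr$maxSteps) break
        idx <- ord[bs:min(bs + tr$batchSize - 1L, length(ord))]
        nMasked <- sum(vapply(cache[idx],
                              function(s) !is.null(s$mask), logical(1)))
        acc <- NULL
        lossClsSum <- 0
        lossShpSum <- 0
        for (i in idx) {
          smp <- cache[[i]]
          img <- smp$image
          msk <- smp$mask
          if (isTRUE(tr$augment)) {
            a <- augmentSample(img, msk)
            img <- a$image
            msk <- a$mask
          }
          needMask <- !is.null(msk) && beta > 0
          fw <- modelForward(model, img, needMask = needMask)
          lc <- if (identical(cfg$loss$type, "cross_entropy"))
            crossEntropy(smp$label, fw$p)
          else
            asymmetricLoss(smp$label, fw$p,
                           asymLossParams(cfg$loss$gammaPlus,
                                          cfg$loss$gammaMinus, cfg$loss$phi))
          lossClsSum <- lossClsSum + lc
          if (needMask) lossShpSum <- lossShpSum + shapeLoss(fw$mask, msk)
          g <- modelBackward(model, fw, smp$label,
                             mask = if (needMask) msk,
                             clsScale = 1 / length(idx),
                             shpScale = if (needMask) beta / nMasked else 0)
          acc <- list(tex = addFlat(acc$tex, g$tex),
                      shp = addFlat(acc$shp, g$shp),
                      dec = if (!is.null(g$dec)) addFlat(acc$dec, g$dec)
                            else acc$dec,
                      fus = addFlat(acc$fus, g$fus))
        }
        flat <- c(stats::setNames(acc$tex, paste0("tex.", names(acc$tex))),
                  stats::setNames(acc$shp, paste0("shp.", names(acc$shp))),
                  if (!is.null(acc$dec))
                    stats::setNames(acc$dec, paste0("dec.", names(acc$dec))),
                  stats::setNames(acc$fus, paste0("fus.", names(acc$fus))))
        upd <- rmspropStep(state, params, flat, tr$lr, tr$weightDecay,
                           tr$momentum, tr$rmspropAlpha)
        state <- upd$state
        params <- upd$params
        modelSetParams(model, params)
        step <- step + 1L
        hist[[step]] <- data.frame(
          step = step, lossCls = lossClsSum / length(idx),
          lossShp = if (nMasked > 0L) lossShpSum / nMasked else 0,
          lr = tr$lr)
      }
      if (nrow(valRows)) {
        rep <- evaluateModel(model, manifest, split = "val")
        f1 <- rep@f1
        if (is.na(bestF1) || f1 > bestF1) {
          bestF1 <- f1
          bestParams <- params
        }
      }
      if (verbose)
        message(sprintf("epoch %d  step %d  L_CLS %.4f  L_SHP %.4f%s",
                        epoch, step, hist[[step]]$lossCls,
                        hist[[step]]$lossShp,
                        if (nrow(valRows))
                          sprintf("  valF1 %.3f (best %.3f)", f1, bestF1)
                        else ""))
      if (step >= tr$maxSteps) break
    }
  })
  if (!is.null(bestParams)) modelSetParams(model, bestParams)
  invisible(list(model = model, history = do.call(rbind, hist),
                 valF1 = bestF1))
}

#' Evaluate a model on a manifest split
#'
#' Accumulates confusion counts at the decision threshold (strictly greater
#' predicts malignant) and derives accuracy, precision, recall and F1.
#'
#' @param model a trained [STNet-class].
#' @param manifest a [LesionManifest-class].
#' @param split split tag to evaluate (`NULL` for all rows).
#' @param threshold decision threshold, default 0.5.
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(model, manifest, split = "test", threshold = 0.5) {
  md <- manifestData(manifest)
  if (!is.null(split) && any(nzchar(md$split)))
    md <- md[md$split %in% split, ]
  if (!nrow(md)) stop("no samples in the requested split")
  size <- model@config$train$imageSize
  probs <- vapply(seq_len(nrow(md)), function(i)
    predictProb(model, loadImage(md$.image[i], size)), numeric(1))
  computeMetrics(confusionCounts(md$label, probs, threshold))
}
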