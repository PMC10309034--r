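#' Build a two-stream shape/texture network
#'
#' Assembles the texture encoder (pyramid-grouped convolutions), the shape
#' encoder (deformable convolutions in the deep stages, offset layers
#' zero-initialized), the mask decoder and the channel-attention fusion head.
#' Weight initialization is seeded He-style, so the same (config, seed) pair
#' always yields the same model.
#'
#' @param config nested configuration list from [stnetConfig()].
#' @param seed integer seed for weight initialization (defaults to
#'   `config$train$seed`).
#' @return an [STNet-class].
#' @export
stnet <- function(config = stnetConfig(), seed = config$train$seed) {
  validateConfig(config)
  env <- new.env(parent = emptyenv())
  withSeed(seed, {
    sched <- config$texture$pgc$schedule
    env$textureEnc <- buildEncoder(
      config$texture$depth, "texture",
      pgcEnabled = isTRUE(config$texture$pgc$enabled),
      pgcSchedule = if (is.numeric(sched)) as.integer(sched) else NULL)
    env$shapeEnc <- buildEncoder(
      config$shape$depth, "shape",
      deformStages = config$shape$deformable$stages)
    env$decoder <- buildDecoder(config$shape$depth,
                                widths = config$shape$decoder$widths)
    env$decoderInGeom <- encoderOutChannels(config$shape$depth)
    env$fusion <- nnFusion(encoderOutChannels(config$texture$depth),
                           encoderOutChannels(config$shape$depth),
                           reduction = config$fusion$reductionRatio,
                           gradScale = config$fusion$gradScale,
                           caffEnabled = isTRUE(config$fusion$caff$enabled))
  })
  if (!is.null(config$texture$pretrainedPath))
    env$textureEnc <- loadBackboneWeightsInto(env$textureEnc,
                                              config$texture$pretrainedPath)
  new("STNet", config = config, modules = env)
}

## Full forward pass for one image. needMask = FALSE skips the decoder.
modelForward <- function(model, image, needMask = TRUE) {
  m <- model@modules
  ft <- nnForward(m$textureEnc, image)
  fs <- nnForward(m$shapeEnc, image)
  fd <- if (needMask) nnForward(m$decoder, fs$y) else NULL
  ff <- fusionForward(m$fusion, ft$y, fs$y)
  list(p = ff$p,
       mask = if (needMask) matrix(fd$y, dim(fd$y)[1L], dim(fd$y)[2L]),
       texFeat = ft$y, shpFeat = fs$y,
       caches = list(tex = ft$cache, shp = fs$cache,
                     dec = if (needMask) fd$cache, fus = ff$cache,
                     maskDim = if (needMask) dim(fd$y)))
}

## Reverse pass for one sample. clsScale / shpScale pre-scale the two loss
## gradients (the trainer uses 1/batch and beta/nMasked). Returns flat grads
## per parameter group; the classification gradient entering the shape
## encoder has already passed the gradient-scaling layer.
modelBackward <- function(model, fw, y, mask = NULL, lossCfg = NULL,
                          clsScale = 1, shpScale = 0) {
  m <- model@modules
  lossCfg <- lossCfg %||% model@config$loss
  p <- fw$p
  dLdp <- if (identical(lossCfg$type, "cross_entropy"))
    crossEntropyGrad(y, p)
  else
    asymmetricLossGrad(y, p, asymLossParams(lossCfg$gammaPlus,
                                            lossCfg$gammaMinus, lossCfg$phi))
  fb <- fusionBackward(m$fusion, fw$caches$fus, dLdp * clsScale)
  gEncOut <- fb$gshp
  gradDec <- NULL
  if (!is.null(mask) && shpScale > 0) {
    npix <- length(fw$mask)
    dmask <- array(2 * (fw$mask - mask) / npix * shpScale, fw$caches$maskDim)
    rd <- nnBackward(m$decoder, fw$caches$dec, dmask)
    gEncOut <- gEncOut + rd$gx
    gradDec <- flattenGrads(m$decoder, rd$grads)
  }
  rt <- nnBackward(m$textureEnc, fw$caches$tex, fb$gtex)
  rs <- nnBackward(m$shapeEnc, fw$caches$shp, gEncOut)
  list(tex = flattenGrads(m$textureEnc, rt$grads),
       shp = flattenGrads(m$shapeEnc, rs$grads),
       dec = gradDec,
       fus = flattenFusionGrads(m$fusion, fb$grads))
}

#' Predict the malignancy probability for one image
#'
#' @param model a trained [STNet-class].
#' @param image array `h x w x 3`, spatial size matching
#'   `config$train$imageSize` (use [loadImage()] to load and resize).
#' @return probability in (0, 1); strictly above 0.5 means malignant.
#' @export
predictProb <- function(model, image) {
  checkImageInput(image)
  modelForward(model, image, needMask = FALSE)$p
}

#' Predict the lesion mask for one image
#'
#' @inheritParams predictProb
#' @return matrix of mask probabilities in (0, 1), input resolution.
#' @export
predictMask <- function(model, image) {
  checkImageInput(image)
  shapeDecode(model, shapeEncode(model, image))
}

## Collect / restore all trainable parameters of a model as one flat list
## (group-prefixed names). Used by the optimizer and the weight hooks.
modelParams <- function(model) {
  m <- model@modules
  c(stats::setNames(flattenParams(m$textureEnc),
                    paste0("tex.", names(flattenParams(m$textureEnc)))),
    stats::setNames(flattenParams(m$shapeEnc),
                    paste0("shp.", names(flattenParams(m$shapeEnc)))),
    stats::setNames(flattenParams(m$decoder),
                    paste0("dec.", names(flattenParams(m$decoder)))),
    stats::setNames(flattenFusionParams(m$fusion),
                    paste0("fus.", names(flattenFusionParams(m$fusion)))))
}

modelSetParams <- function(model, flat) {
  m <- model@modules
  strip <- function(prefix) {
    keep <- startsWith(names(flat), prefix)
    stats::setNames(flat[keep], substring(names(flat)[keep],
                                          nchar(prefix) + 1L))
  }
  m$textureEnc <- unflattenParams(m$textureEnc, strip("tex."))
  m$shapeEnc <- unflattenParams(m$shapeEnc, strip("shp."))
  m$decoder <- unflattenParams(m$decoder, strip("dec."))
  m$fusion <- unflattenFusionParams(m$fusion, strip("fus."))
  invisible(model)
}

#' Save / restore a model snapshot
#'
#' `saveModel()` writes the configuration and a flat named parameter list to
#' an RDS file; `loadModel()` rebuilds the architecture from the stored
#' configuration and restores the parameters, returning a model identical in
#' behavior to the saved one.
#'
#' @param model an [STNet-class].
#' @param path RDS file path.
#' @return `saveModel()` the path invisibly; `loadModel()` an
#'   [STNet-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(list(config = model@config, params = modelParams(model)), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  snap <- readRDS(path)
  model <- stnet(snap$config)
  modelSetParams(model, snap$params)
  model
}

#' Load externally supplied backbone weights into the texture encoder
#'
#' Plumbing hook for transfer learning: reads an RDS file holding a flat
#' named parameter list (as produced by saving the `tex.`-prefixed entries of
#' a model's parameters) and writes every matching entry into the texture
#' encoder. Entries with unknown names or mismatching shapes are skipped
#' with a warning.
#'
#' @param model an [STNet-class].
#' @param path RDS file path.
#' @return the model, invisibly (modified in place).
#' @export
loadBackboneWeights <- function(model, path) {
  model@modules$textureEnc <- loadBackboneWeightsInto(
    model@modules$textureEnc, path)
  invisible(model)
}

loadBackboneWeightsInto <- function(enc, path) {
  flat <- readRDS(path)
  names(flat) <- sub("^tex\\.", "", names(flat))
  have <- flattenParams(enc)
  ok <- intersect(names(flat), names(have))
  bad <- ok[vapply(ok, function(nm)
    length(flat[[nm]]) != length(have[[nm]]), logical(1))]
  if (length(bad) || length(setdiff(names(flat), names(have))))
    warning("some supplied weights were skipped (unknown name or shape)")
  ok <- setdiff(ok, bad)
  unflattenParams(enc, flat[ok])
}
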