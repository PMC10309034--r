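#' Manifest of lesion images, masks and labels
#'
#' Binds images, optional segmentation masks and binary class labels together
#' with an optional train/val/test split tag. Paths in `data` are relative to
#' `dir`. Rows with an empty `mask` field carry no mask; training then skips
#' the shape-supervision term for those samples.
#'
#' @slot data data.frame with columns `image`, `mask`, `label`, `split`.
#' @slot dir root directory the paths are resolved against.
#' @exportClass LesionManifest
setClass("LesionManifest",
         representation(data = "data.frame", dir = "character"))

setValidity("LesionManifest", function(object) {
  d <- object@data
  need <- c("image", "mask", "label", "split")
  if (!all(need %in% names(d)))
    return(paste("manifest must have columns:", paste(need, collapse = ", ")))
  if (nrow(d) && !all(d$label %in% c(0L, 1L)))
    return("labels must be 0 (benign) or 1 (malignant)")
  if (nrow(d) && any(!nzchar(d$image)))
    return("every row needs an image path")
  TRUE
})

#' Two-stream shape/texture network
#'
#' Holds the model configuration and an environment with the four parameter
#' groups: texture encoder, shape encoder, mask decoder and fusion head.
#' The environment gives the trainer reference semantics, so
#' [trainModel()] updates the object in place as well as returning it.
#'
#' @slot config nested configuration list, see [stnetConfig()].
#' @slot modules environment with `textureEnc`, `shapeEnc`, `decoder`,
#'   `fusion`.
#' @exportClass STNet
setClass("STNet", representation(config = "list", modules = "environment"))

#' Classification evaluation report
#'
#' Accuracy, precision, recall and F1 derived from confusion counts with the
#' conventions: positives are malignant; a probability strictly above the
#' threshold predicts positive; precision (recall) is 0 when its denominator
#' is 0.
#'
#' @slot accuracy,precision,recall,f1 numeric scalars in \[0, 1\].
#' @slot counts named integer vector (TP, FP, TN, FN).
#' @exportClass EvalReport
setClass("EvalReport",
         representation(accuracy = "numeric", precision = "numeric",
                        recall = "numeric", f1 = "numeric",
                        counts = "integer"))

setValidity("EvalReport", function(object) {
  if (!identical(names(object@counts), c("TP", "FP", "TN", "FN")))
    return("counts must be named TP, FP, TN, FN")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  TRUE
})
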