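#' @export
setGeneric("manifestData", function(x) standardGeneric("manifestData"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))

#' Accessors for LesionManifest
#'
#' `manifestData()` returns the underlying data.frame (with an extra
#' `.image` / `.mask` column of resolved absolute paths), `nSamples()` the
#' row count and `classCounts()` the per-label tally.
#'
#' @param x a [LesionManifest-class]
#' @return see above
#' @rdname LesionManifest-accessors
#' @aliases manifestData nSamples classCounts
#' @export
setMethod("manifestData", "LesionManifest", function(x) {
  d <- x@data
  d$.image <- file.path(x@dir, d$image)
  d$.mask <- ifelse(nzchar(d$mask), file.path(x@dir, d$mask), "")
  d
})

#' @rdname LesionManifest-accessors
#' @export
setMethod("nSamples", "LesionManifest", function(x) nrow(x@data))

#' @rdname LesionManifest-accessors
#' @export
setMethod("classCounts", "LesionManifest", function(x)
  c(benign = sum(x@data$label == 0L), malignant = sum(x@data$label == 1L)))

setMethod("show", "LesionManifest", function(object) {
  cc <- classCounts(object)
  nm <- sum(nzchar(object@data$mask))
  cat("LesionManifest:", nrow(object@data), "samples (",
      cc["malignant"], "malignant /", cc["benign"], "benign ),",
      nm, "with masks\n")
  if (any(nzchar(object@data$split))) {
    tb <- table(factor(object@data$split,
                       levels = c("train", "val", "test")))
    cat("  splits:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  cat("  dir:", object@dir, "\n")
})

#' `reportMetrics()` returns the four metrics as a named numeric vector.
#'
#' @param x an [EvalReport-class]
#' @rdname EvalReport-accessors
#' @aliases reportMetrics
#' @export
setMethod("reportMetrics", "EvalReport", function(x)
  c(accuracy = x@accuracy, precision = x@precision,
    recall = x@recall, f1 = x@f1))

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport: Acc %.4f  Pre %.4f  Rec %.4f  F1 %.4f  (TP %d FP %d TN %d FN %d)\n",
    object@accuracy, object@precision, object@recall, object@f1,
    object@counts["TP"], object@counts["FP"], object@counts["TN"],
    object@counts["FN"]))
})

setMethod("show", "STNet", function(object) {
  cfg <- object@config
  np <- sum(vapply(flattenParams(object@modules$textureEnc), length, 1L)) +
    sum(vapply(flattenParams(object@modules$shapeEnc), length, 1L)) +
    sum(vapply(flattenParams(object@modules$decoder), length, 1L)) +
    sum(vapply(flattenParams(object@modules$fusion$caff %||% list(kind = "seq", layers = list())), length, 1L)) +
    length(object@modules$fusion$fc$params$w) + 1L
  cat("STNet two-stream model\n")
  cat("  texture encoder : depth", cfg$texture$depth,
      if (isTRUE(cfg$texture$pgc$enabled)) "(pyramid-grouped conv)" else "(standard conv)", "\n")
  cat("  shape encoder   : depth", cfg$shape$depth, "with deformable stages\n")
  cat("  fusion          : channel attention",
      if (isTRUE(cfg$fusion$caff$enabled)) "on," else "off,",
      "gradient scale", cfg$fusion$gradScale, "\n")
  cat("  parameters      :", format(np, big.mark = ","), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
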