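## Seeded stratified fold assignment: every sample lands in exactly one of k
## folds; within each class the fold sizes differ by at most one.
cvFolds <- function(labels, k, seed) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > min(table(labels)))
    stop("k exceeds the number of samples in the smaller class")
  folds <- integer(length(labels))
  withSeed(seed, {
    for (lb in unique(labels)) {
      idx <- which(labels == lb)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Stratified k-fold cross-validation
#'
#' Partitions the manifest into k mutually exclusive, exhaustive,
#' class-stratified folds; trains a fresh seeded model on k-1 folds and
#' evaluates on the held-out fold. F1 is the headline metric under class
#' imbalance, but all four metrics are reported per fold.
#'
#' @param manifest a [LesionManifest-class].
#' @param k number of folds, `>= 2` and at most the size of the smaller
#'   class.
#' @param config configuration for the per-fold models (e.g.
#'   [stnetTinyConfig()]).
#' @param seed seed controlling fold assignment and per-fold model seeds.
#' @return data.frame with columns `fold`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
crossValidate <- function(manifest, k = 5L, config = stnetTinyConfig(),
                          seed = 1L) {
  k <- as.integer(k)
  d <- manifest@data
  folds <- cvFolds(d$label, k, seed)
  out <- vector("list", k)
  for (f in seq_len(k)) {
    d2 <- d
    d2$split <- ifelse(folds == f, "test", "train")
    man2 <- new("LesionManifest", data = d2, dir = manifest@dir)
    cfg <- config
    cfg$train$seed <- as.integer(seed + f)
    model <- stnet(cfg)
    trainModel(model, man2)
    rep <- evaluateModel(model, man2, split = "test")
    out[[f]] <- data.frame(fold = f, accuracy = rep@accuracy,
                           precision = rep@precision, recall = rep@recall,
                           f1 = rep@f1)
  }
  do.call(rbind, out)
}

#' Sensitivity sweep over the negative focusing factor
#'
#' Trains one seeded model per requested `gammaMinus` value (with
#' `gammaPlus` and everything else held at the supplied config) and
#' tabulates the four evaluation metrics on the manifest's `val` split when
#' present, otherwise `test`.
#'
#' @param manifest a split-tagged [LesionManifest-class].
#' @param gammaMinusValues numeric vector of focusing factors, `>= 0`.
#' @param config base configuration.
#' @param seed model/training seed shared across the sweep rows.
#' @param outCsv optional path; the table is also written there as CSV.
#' @return data.frame with columns `gammaMinus`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
gammaSweep <- function(manifest, gammaMinusValues, config = stnetTinyConfig(),
                       seed = 1L, outCsv = NULL) {
  stopifnot(all(gammaMinusValues >= 0))
  evalSplit <- if (any(manifest@data$split == "val")) "val" else "test"
  out <- vector("list", length(gammaMinusValues))
  for (i in seq_along(gammaMinusValues)) {
    cfg <- config
    cfg$loss$gammaMinus <- gammaMinusValues[i]
    cfg$train$seed <- as.integer(seed)
    model <- stnet(cfg)
    suppressWarnings(trainModel(model, manifest))
    rep <- evaluateModel(model, manifest, split = evalSplit)
    out[[i]] <- data.frame(gammaMinus = gammaMinusValues[i],
                           accuracy = rep@accuracy,
                           precision = rep@precision,
                           recall = rep@recall, f1 = rep@f1)
  }
  tab <- do.call(rbind, out)
  if (!is.null(outCsv)) utils::write.csv(tab, outCsv, row.names = FALSE)
  tab
}
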