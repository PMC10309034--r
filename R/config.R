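#' Model and training configuration
#'
#' Builds the nested configuration list consumed by [stnet()] and
#' [trainModel()]. Arguments given here are merged (recursively) over the
#' defaults, e.g. `stnetConfig(texture = list(depth = 101))`.
#'
#' Sections and notable keys:
#' * `texture`: `depth` (8, 50, 101), `pgc$enabled`, `pgc$schedule`
#'   (`"geometric"` or an integer vector of three group counts),
#'   `pretrainedPath` (optional backbone weight file, see
#'   [loadBackboneWeights()]).
#' * `shape`: `depth`, `deformable$stages` (`"deep"`, `"all"` or stage
#'   indices), `decoder$widths`.
#' * `fusion`: `reductionRatio` (channel-attention bottleneck, default 16),
#'   `gradScale` (the alpha damping classification gradients into the shape
#'   encoder, default 0.1), `caff$enabled`.
#' * `loss`: `type` (`"asymmetric"` or `"cross_entropy"`), `gammaPlus` (1),
#'   `gammaMinus` (3), `phi` (0.05), `alpha` (synonym of
#'   `fusion$gradScale`), `beta` (shape-loss weight, 1).
#' * `train`: `imageSize` (224), `batchSize` (64), `lr` (5e-4),
#'   `weightDecay` (1e-5), `momentum` (0.9), `epochs`, `seed`,
#'   `optimizer` (`"rmsprop"`), `maxSteps`, `augment`.
#'
#' @param ... named sections merged over the defaults.
#' @return nested configuration list.
#' @export
stnetConfig <- function(...) {
  defaults <- list(
    texture = list(depth = 50L,
                   pgc = list(enabled = TRUE, schedule = "geometric"),
                   pretrainedPath = NULL),
    shape = list(depth = 50L,
                 deformable = list(stages = "deep"),
                 decoder = list(widths = NULL)),
    fusion = list(reductionRatio = 16L, gradScale = 0.1,
                  caff = list(enabled = TRUE)),
    loss = list(type = "asymmetric", gammaPlus = 1, gammaMinus = 3,
                phi = 0.05, alpha = 0.1, beta = 1),
    train = list(imageSize = 224L, batchSize = 64L, lr = 5e-4,
                 weightDecay = 1e-5, momentum = 0.9, epochs = 10L,
                 seed = 1L, optimizer = "rmsprop", maxSteps = Inf,
                 augment = TRUE, rmspropAlpha = 0.99)
  )
  over <- list(...)
  cfg <- utils::modifyList(defaults, over)
  # alpha and fusion$gradScale are the same dial; whichever the user set wins
  userAlpha <- !is.null(over$loss$alpha)
  userGS <- !is.null(over$fusion$gradScale)
  if (userAlpha && !userGS) cfg$fusion$gradScale <- cfg$loss$alpha
  if (userGS && !userAlpha) cfg$loss$alpha <- cfg$fusion$gradScale
  if (userAlpha && userGS && cfg$loss$alpha != cfg$fusion$gradScale)
    stop("loss$alpha and fusion$gradScale are the same quantity; set one")
  validateConfig(cfg)
  cfg
}

#' Desk-scale configuration
#'
#' Depth-8 encoders, 64-pixel images, batch 8 and a larger learning rate:
#' the profile used by the package's own tests and examples so every
#' end-to-end run completes in minutes on one CPU core.
#'
#' @param seed training seed.
#' @param ... further overrides, as in [stnetConfig()].
#' @return nested configuration list.
#' @export
stnetTinyConfig <- function(seed = 1L, ...) {
  base <- stnetConfig(
    texture = list(depth = 8L),
    shape = list(depth = 8L),
    train = list(imageSize = 64L, batchSize = 8L, lr = 2e-3,
                 epochs = 25L, seed = as.integer(seed), augment = FALSE))
  over <- list(...)
  if (length(over)) {
    cfg <- utils::modifyList(base, over)
    validateConfig(cfg)
    cfg
  } else base
}

validateConfig <- function(cfg) {
  tr <- cfg$train
  stopifnot(tr$imageSize >= 32L, tr$batchSize >= 1L, tr$lr > 0,
            tr$weightDecay >= 0, tr$momentum >= 0, tr$momentum < 1,
            tr$epochs >= 1L)
  stopifnot(cfg$fusion$gradScale > 0, cfg$fusion$reductionRatio >= 1)
  stopifnot(cfg$loss$beta >= 0, cfg$loss$gammaPlus >= 0,
            cfg$loss$gammaMinus >= 0, cfg$loss$phi >= 0, cfg$loss$phi < 1)
  if (!cfg$loss$type %in% c("asymmetric", "cross_entropy"))
    stop("loss$type must be 'asymmetric' or 'cross_entropy'")
  aTex <- archSpec(cfg$texture$depth)
  aShp <- archSpec(cfg$shape$depth)
  if (aTex$factor != aShp$factor)
    stop("texture and shape encoders must share the downsampling factor")
  if (tr$imageSize %% aTex$factor != 0L)
    stop("image size must be divisible by the backbone downsampling factor")
  invisible(cfg)
}

#' Read a configuration from YAML
#'
#' The file holds any subset of the sections of [stnetConfig()]; missing
#' keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
readConfigYAML <- function(path) {
  do.call(stnetConfig, yaml::read_yaml(path))
}
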