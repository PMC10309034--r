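## Synthetic lesion images: a star-shaped lesion whose boundary is a circle
## perturbed by a truncated Fourier series (orders 2-8), class-dependent
## speckle texture inside the lesion, smooth illumination gradient outside.
## Everything is a pure function of (spec, seed).

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of one synthetic lesion image
#'
#' @param seed integer RNG seed; the same spec always renders bit-identical
#'   arrays.
#' @param label 0 (benign) or 1 (malignant). The label does not change the
#'   renderer; class-conditional appearance comes from how
#'   [generateDataset()] samples `irregularity` and `textureContrast` per
#'   class.
#' @param imageSize square image side in pixels, `>= 32`.
#' @param irregularity boundary radial-perturbation amplitude, `>= 0`;
#'   0 renders a discretized circle.
#' @param textureContrast standard deviation of the within-lesion intensity
#'   speckle, `>= 0`.
#' @param baseRadiusFrac lesion radius as a fraction of the image side,
#'   in (0, 0.5).
#' @return a validated list of class `"LesionSpec"`.
#' @export
lesionSpec <- function(seed, label, imageSize = 64L, irregularity = 0,
                       textureContrast = 0.05, baseRadiusFrac = 0.3) {
  imageSize <- as.integer(imageSize)
  if (is.na(imageSize) || imageSize < 32L) stop("imageSize must be >= 32")
  if (!(label %in% c(0L, 1L))) stop("label must be 0 or 1")
  if (baseRadiusFrac <= 0 || baseRadiusFrac >= 0.5)
    stop("baseRadiusFrac must lie in (0, 0.5)")
  if (irregularity < 0 || textureContrast < 0)
    stop("irregularity and textureContrast must be >= 0")
  structure(list(seed = as.integer(seed), label = as.integer(label),
                 imageSize = imageSize, irregularity = irregularity,
                 textureContrast = textureContrast,
                 baseRadiusFrac = baseRadiusFrac),
            class = "LesionSpec")
}

#' Render one synthetic lesion image and its mask
#'
#' The lesion boundary is `r(theta) = R * (1 + irregularity * f(theta))`
#' where `f` is a seeded truncated Fourier series over angular orders 2-8,
#' normalized to peak amplitude 1, so the domain is star-shaped (hence simply
#' connected) whenever `irregularity < 1`. Interior pixels carry a darker
#' base color plus Gaussian luminance speckle with standard deviation
#' `textureContrast`; the background is a skin-toned linear illumination
#' gradient in a seeded random direction.
#'
#' @param spec a [lesionSpec()].
#' @return list with `image` (array `s x s x 3`, values in \[0, 1\]) and
#'   `mask` (matrix `s x s`, values in `{0, 1}`).
#' @export
generateLesion <- function(spec) {
  stopifnot(inherits(spec, "LesionSpec"))
  s <- spec$imageSize
  withSeed(spec$seed, {
    orders <- 2:8
    amp <- stats::rnorm(length(orders))
    phase <- stats::runif(length(orders), 0, 2 * pi)
    ctr <- (s - 1) / 2 + stats::runif(2, -0.02, 0.02) * s
    gradDir <- stats::runif(1, 0, 2 * pi)
    lesionCol <- c(0.45, 0.30, 0.20) + stats::runif(3, -0.05, 0.05)
    noise <- matrix(stats::rnorm(s * s), s, s)

    xs <- matrix(rep(seq_len(s) - 1, s), s, s)        # rows
    ys <- t(xs)                                       # cols
    dx <- xs - ctr[1]
    dy <- ys - ctr[2]
    theta <- atan2(dy, dx)
    dist <- sqrt(dx * dx + dy * dy)

    pert <- matrix(0, s, s)
    for (i in seq_along(orders))
      pert <- pert + amp[i] * cos(orders[i] * theta + phase[i])
    # normalize on a dense angular grid so irregularity is the exact peak
    # relative amplitude of the radial perturbation
    tg <- seq(0, 2 * pi, length.out = 720L)
    pg <- rowSums(sapply(seq_along(orders),
                         function(i) amp[i] * cos(orders[i] * tg + phase[i])))
    peak <- max(abs(pg))
    if (peak > 0) pert <- pert / peak
    R <- spec$baseRadiusFrac * s
    rTheta <- R * (1 + spec$irregularity * pert)
    mask <- (dist <= rTheta) * 1

    base <- c(0.85, 0.72, 0.62)
    grad <- (cos(gradDir) * dx + sin(gradDir) * dy) / s * 0.12
    img <- array(0, c(s, s, 3))
    speckle <- noise * spec$textureContrast
    for (ch in 1:3) {
      bg <- base[ch] + grad
      inside <- lesionCol[ch] + speckle
      img[, , ch] <- pmin(pmax(bg * (1 - mask) + inside * mask, 0), 1)
    }
    list(image = img, mask = mask)
  })
}

#' Radial variance of a mask boundary
#'
#' Boundary pixels are mask pixels with at least one 4-neighbor outside the
#' mask; the statistic is the variance of their distances to the mask
#' centroid. It separates irregular from circular boundaries and is the
#' shape cue the synthetic classes are built on.
#'
#' @param mask binary matrix.
#' @return scalar variance (0 for an exact circle up to discretization).
#' @export
boundaryRadialVariance <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask > 0
  if (!any(m)) return(0)
  pad <- function(sh) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    src <- m
    if (sh == "up") out[-nrow(m), ] <- src[-1, ]
    if (sh == "down") out[-1, ] <- src[-nrow(m), ]
    if (sh == "left") out[, -ncol(m)] <- src[, -1]
    if (sh == "right") out[, -1] <- src[, -ncol(m)]
    out
  }
  interior <- pad("up") & pad("down") & pad("left") & pad("right")
  boundary <- m & !interior
  idx <- which(boundary, arr.ind = TRUE)
  cm <- colMeans(which(m, arr.ind = TRUE))
  d <- sqrt((idx[, 1] - cm[1])^2 + (idx[, 2] - cm[2])^2)
  if (length(d) < 2L) 0 else stats::var(d)
}

defaultClassParams <- function() {
  list(malignantIrregularity = c(0.25, 0.50),
       benignIrregularity = c(0.00, 0.15),
       malignantTexture = c(0.10, 0.20),
       benignTexture = c(0.02, 0.08),
       radiusFrac = c(0.20, 0.35))
}

#' Generate a synthetic lesion dataset on disk
#'
#' Writes `nMalignant + nBenign` RGB PNG images (and masks for a seeded
#' subset of `floor(maskFraction * n)` samples, as 8-bit grayscale PNGs with
#' values 0/255) plus a CSV manifest `manifest.csv` with header
#' `image,mask,label,split`. Malignant lesions draw higher boundary
#' irregularity and stronger speckle than benign ones (ranges in
#' `classParams`), so both a shape cue and a texture cue are informative by
#' construction. The default malignant:benign call mirrors the roughly 1:2.85
#' imbalance of real dermoscopy archives.
#'
#' @param nMalignant,nBenign per-class sample counts, `>= 1`.
#' @param maskFraction fraction of samples that carry a mask, in `[0, 1]`.
#' @param imageSize square image side, `>= 32`.
#' @param seed integer seed controlling every random choice.
#' @param outDir output directory (created if needed).
#' @param classParams class-conditional parameter ranges, see
#'   `defaultClassParams` in the sources.
#' @return a [LesionManifest-class].
#' @export
generateDataset <- function(nMalignant, nBenign, maskFraction = 0.15,
                            imageSize = 64L, seed = 1L, outDir,
                            classParams = defaultClassParams()) {
  stopifnot(nMalignant >= 1L, nBenign >= 1L,
            maskFraction >= 0, maskFraction <= 1)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  n <- nMalignant + nBenign
  labels <- c(rep(1L, nMalignant), rep(0L, nBenign))
  withSeed(seed, {
    ord <- sample.int(n)
    labels <- labels[ord]
    irr <- ifelse(labels == 1L,
                  stats::runif(n, classParams$malignantIrregularity[1],
                               classParams$malignantIrregularity[2]),
                  stats::runif(n, classParams$benignIrregularity[1],
                               classParams$benignIrregularity[2]))
    tex <- ifelse(labels == 1L,
                  stats::runif(n, classParams$malignantTexture[1],
                               classParams$malignantTexture[2]),
                  stats::runif(n, classParams$benignTexture[1],
                               classParams$benignTexture[2]))
    rad <- stats::runif(n, classParams$radiusFrac[1], classParams$radiusFrac[2])
    nMask <- floor(maskFraction * n)
    maskRows <- sort(sample.int(n, nMask))
    seeds <- (as.numeric(seed) * 10007 + seq_len(n) * 7919) %% 2147483647
    rows <- data.frame(image = sprintf("img_%04d.png", seq_len(n)),
                       mask = "", label = labels, split = "",
                       stringsAsFactors = FALSE)
    rows$mask[maskRows] <- sprintf("mask_%04d.png", maskRows)
    for (i in seq_len(n)) {
      sp <- lesionSpec(seeds[i], labels[i], imageSize, irr[i], tex[i], rad[i])
      les <- generateLesion(sp)
      png::writePNG(les$image, file.path(outDir, rows$image[i]))
      if (nzchar(rows$mask[i]))
        png::writePNG(les$mask, file.path(outDir, rows$mask[i]))
    }
    man <- new("LesionManifest", data = rows, dir = normalizePath(outDir))
    writeManifest(man)
    man
  })
}

#' Write / read a manifest CSV
#'
#' The CSV (header `image,mask,label,split`, empty `mask` meaning no mask)
#' lives alongside the images it references.
#'
#' @param manifest a [LesionManifest-class].
#' @param file CSV path; defaults to `manifest.csv` inside the manifest dir.
#' @return `writeManifest()` the path, invisibly; `readManifest()` a
#'   [LesionManifest-class].
#' @export
writeManifest <- function(manifest, file = file.path(manifest@dir,
                                                     "manifest.csv")) {
  utils::write.csv(manifest@data, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeManifest
#' @param dir directory the image paths are relative to (defaults to the
#'   CSV's directory).
#' @export
readManifest <- function(file, dir = dirname(file)) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = c(image = "character",
                                      mask = "character",
                                      split = "character"))
  d$mask[is.na(d$mask)] <- ""
  d$split[is.na(d$split)] <- ""
  man <- new("LesionManifest", data = d, dir = normalizePath(dir))
  md <- manifestData(man)
  if (!all(file.exists(md$.image)))
    stop("manifest references missing image files")
  man
}

#' Assign train/validation/test split tags
#'
#' Largest-remainder apportionment of the (normalized) ratios; with
#' `stratify = TRUE` the apportionment runs per class so each split's class
#' ratio tracks the dataset's. Assignment within a class is a seeded
#' permutation. Splits are disjoint and exhaustive.
#'
#' @param manifest a [LesionManifest-class].
#' @param ratios length-3 positive vector (train, val, test); normalized to
#'   sum to 1.
#' @param seed integer seed for the permutation.
#' @param stratify stratify by class label (default TRUE).
#' @return the manifest with `split` tags filled in.
#' @export
splitManifest <- function(manifest, ratios = c(0.6, 0.2, 0.2), seed = 1L,
                          stratify = TRUE) {
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) <= 0)
    stop("ratios must be three non-negative numbers with positive sum")
  ratios <- ratios / sum(ratios)
  n <- nSamples(manifest)
  if (n < sum(ratios > 0)) stop("fewer samples than requested splits")
  tags <- c("train", "val", "test")
  apportion <- function(m) {
    target <- ratios * m
    base <- floor(target)
    rem <- m - sum(base)
    if (rem > 0) {
      frac <- target - base
      extra <- order(frac, -seq_along(frac), decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    base
  }
  d <- manifest@data
  withSeed(seed, {
    groups <- if (stratify) split(seq_len(n), d$label) else list(seq_len(n))
    for (idx in groups) {
      sizes <- apportion(length(idx))
      perm <- idx[sample.int(length(idx))]
      d$split[perm] <- rep(tags, times = sizes)
    }
  })
  new("LesionManifest", data = d, dir = manifest@dir)
}

#' Subset a manifest by split tag
#'
#' @param manifest a [LesionManifest-class].
#' @param split one of `"train"`, `"val"`, `"test"`, or `NULL` for all rows.
#' @return a [LesionManifest-class] with the selected rows.
#' @export
manifestSplit <- function(manifest, split = NULL) {
  if (is.null(split)) return(manifest)
  new("LesionManifest", data = manifest@data[manifest@data$split %in% split, ,
                                             drop = FALSE],
      dir = manifest@dir)
}
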