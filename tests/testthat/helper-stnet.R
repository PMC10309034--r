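# Shared fixtures and oracles. Datasets are generated once per session and
# cached under tempdir().

.fixtures <- new.env(parent = emptyenv())

fixtureDataset <- function(name, nMal, nBen, maskFraction, seed,
                           imageSize = 64L, classParams = NULL) {
  key <- paste0(name, "-", seed)
  if (is.null(.fixtures[[key]])) {
    dir <- file.path(tempdir(), paste0("stnet-fix-", key))
    args <- list(nMalignant = nMal, nBenign = nBen,
                 maskFraction = maskFraction, imageSize = imageSize,
                 seed = seed, outDir = dir)
    if (!is.null(classParams)) args$classParams <- classParams
    .fixtures[[key]] <- do.call(generateDataset, args)
  }
  .fixtures[[key]]
}

# Loop-based grouped convolution, the independent oracle for the GEMM path.
bruteGroupedConv <- function(x, w, groups = 1L, stride = 1L, pad = 1L) {
  kh <- dim(w)[1L]; kw <- dim(w)[2L]; cing <- dim(w)[3L]; cout <- dim(w)[4L]
  H <- dim(x)[1L]; W <- dim(x)[2L]; cin <- dim(x)[3L]
  coutg <- cout %/% groups
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  Ho <- (H + 2 * pad - kh) %/% stride + 1L
  Wo <- (W + 2 * pad - kw) %/% stride + 1L
  y <- array(0, c(Ho, Wo, cout))
  for (co in seq_len(cout)) {
    g <- (co - 1L) %/% coutg
    for (r in seq_len(Ho)) for (c in seq_len(Wo)) {
      acc <- 0
      for (ci in seq_len(cing)) for (ki in seq_len(kh)) for (kj in seq_len(kw))
        acc <- acc + w[ki, kj, ci, co] *
          xp[(r - 1L) * stride + ki, (c - 1L) * stride + kj, g * cing + ci]
      y[r, c, co] <- acc
    }
  }
  y
}

# Central finite differences of a scalar function of a flat numeric vector.
numericGrad <- function(f, x, h = 1e-3) {
  vapply(seq_along(x), function(i) {
    x1 <- x; x1[i] <- x[i] + h
    x2 <- x; x2[i] <- x[i] - h
    (f(x1) - f(x2)) / (2 * h)
  }, numeric(1))
}

# Replace every deformable conv by the plain conv with the same main weights
# (used to verify the zero-offset reduction at initialization).
stripDeform <- function(m) {
  if (identical(m$kind, "dconv")) {
    return(list(kind = "conv",
                params = m$params[intersect(c("w", "b"), names(m$params))],
                stride = m$stride, pad = m$pad, groups = 1L))
  }
  if (identical(m$kind, "seq")) {
    m$layers <- lapply(m$layers, stripDeform)
  } else if (identical(m$kind, "block")) {
    m$body <- stripDeform(m$body)
    if (!is.null(m$shortcut)) m$shortcut <- stripDeform(m$shortcut)
  }
  m
}

# Number of 4-connected foreground components (for mask connectivity checks).
countComponents <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] == 1 && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
              m[q[1], q[2]] == 1 && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
    }
  }
  cur
}

randomImage <- function(size = 64L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::runif(size * size * 3), c(size, size, 3L))
}
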