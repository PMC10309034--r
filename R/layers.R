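## Internal layer graph.
##
## A module is a plain list with a `kind` field; trainable arrays live in
## `$params`. Containers: kind "seq" (field `layers`) and kind "block"
## (residual: fields `body`, `shortcut`). nnForward() returns list(y, cache);
## nnBackward() returns list(gx, grads) with `grads` mirroring the module
## tree, so flattenParams()/flattenGrads() produce aligned named lists for
## the optimizer.

rnormArray <- function(dims, sd) array(stats::rnorm(prod(dims), 0, sd), dims)

wAs3d <- function(w) {
  d <- dim(w)
  array(w, c(d[1L], d[2L], d[3L] * d[4L]))
}

nnConv <- function(cin, cout, k, stride = 1L, pad = k %/% 2L, groups = 1L,
                   bias = TRUE, wsd = sqrt(2 / (k * k * cin / groups))) {
  if (cin %% groups != 0L || cout %% groups != 0L)
    stop("groups must divide the input and output channel counts")
  p <- list(w = rnormArray(c(k, k, cin %/% groups, cout), wsd))
  if (bias) p$b <- numeric(cout)
  list(kind = "conv", params = p, stride = as.integer(stride),
       pad = as.integer(pad), groups = as.integer(groups))
}

## Deformable conv: carries its own offset-predicting conv (zero-initialized,
## so the layer starts exactly non-deformable).
nnDConv <- function(cin, cout, k, stride = 1L, pad = k %/% 2L, bias = TRUE) {
  p <- list(w = rnormArray(c(k, k, cin, cout), sqrt(2 / (k * k * cin))),
            w_off = array(0, c(k, k, cin, 2L * k * k)),
            b_off = numeric(2L * k * k))
  if (bias) p$b <- numeric(cout)
  list(kind = "dconv", params = p, stride = as.integer(stride),
       pad = as.integer(pad))
}

nnTConv <- function(cin, cout, k = 4L, stride = 2L, pad = 1L, bias = TRUE) {
  p <- list(w = rnormArray(c(k, k, cout, cin), sqrt(2 / (k * k * cin))))
  if (bias) p$b <- numeric(cout)
  list(kind = "tconv", params = p, stride = as.integer(stride),
       pad = as.integer(pad))
}

nnINorm <- function(c, eps = 1e-5)
  list(kind = "inorm", params = list(gamma = rep(1, c), beta = numeric(c)),
       eps = eps)

nnReLU <- function() list(kind = "relu", params = list())
nnSigmoid <- function() list(kind = "sigmoid", params = list())
nnMaxPool <- function(k = 3L, stride = 2L, pad = 1L)
  list(kind = "maxpool", params = list(), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))

nnDense <- function(nin, nout, wsd = sqrt(2 / nin))
  list(kind = "dense",
       params = list(w = matrix(stats::rnorm(nin * nout, 0, wsd), nin, nout),
                     b = numeric(nout)))

## Identity forward; multiplies the backpropagated gradient by `factor`.
nnGScale <- function(factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("gradient scale factor must be a positive scalar")
  list(kind = "gscale", params = list(), factor = factor)
}

nnSeq <- function(...) list(kind = "seq", layers = list(...))

nnBlock <- function(body, shortcut = NULL)
  list(kind = "block", body = body, shortcut = shortcut)

sigmoidFn <- function(x) 1 / (1 + exp(-x))

nnForward <- function(m, x) {
  switch(m$kind,
    conv = {
      b <- if (is.null(m$params[["b"]])) numeric(0) else m$params[["b"]]
      y <- conv2d_fwd(x, wAs3d(m$params$w), dim(m$params$w), b,
                      m$stride, m$pad, m$groups)
      list(y = y, cache = list(x = x))
    },
    dconv = {
      w <- m$params$w
      off <- conv2d_fwd(x, wAs3d(m$params$w_off), dim(m$params$w_off),
                        m$params$b_off, m$stride, m$pad, 1L)
      b <- if (is.null(m$params[["b"]])) numeric(0) else m$params[["b"]]
      y <- dconv2d_fwd(x, wAs3d(w), dim(w), b, off, m$stride, m$pad)
      list(y = y, cache = list(x = x, off = off))
    },
    tconv = {
      b <- if (is.null(m$params[["b"]])) numeric(0) else m$params[["b"]]
      y <- tconv2d_fwd(x, wAs3d(m$params$w), dim(m$params$w), b,
                       m$stride, m$pad)
      list(y = y, cache = list(x = x))
    },
    inorm = {
      d <- dim(x); n <- d[1L] * d[2L]
      xm <- matrix(x, n, d[3L])
      mu <- colMeans(xm)
      v <- colMeans(xm * xm) - mu * mu
      s <- sqrt(pmax(v, 0) + m$eps)
      xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, s, "/")
      y <- sweep(sweep(xhat, 2L, m$params$gamma, "*"), 2L, m$params$beta, "+")
      list(y = array(y, d), cache = list(xhat = xhat, s = s, d = d))
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = list(mask = mask))
    },
    sigmoid = {
      y <- sigmoidFn(x)
      list(y = y, cache = list(y = y))
    },
    maxpool = {
      r <- maxpool_fwd(x, m$k, m$stride, m$pad)
      list(y = r$y, cache = list(idx = r$idx, H = dim(x)[1L], W = dim(x)[2L]))
    },
    dense = {
      y <- drop(crossprod(m$params$w, as.numeric(x))) + m$params[["b"]]
      list(y = y, cache = list(x = as.numeric(x)))
    },
    gscale = list(y = x, cache = NULL),
    seq = {
      caches <- vector("list", length(m$layers))
      for (i in seq_along(m$layers)) {
        r <- nnForward(m$layers[[i]], x)
        x <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x, cache = caches)
    },
    block = {
      rb <- nnForward(m$body, x)
      if (is.null(m$shortcut)) {
        sc <- x
        rs <- NULL
      } else {
        rs <- nnForward(m$shortcut, x)
        sc <- rs$y
      }
      pre <- rb$y + sc
      mask <- pre > 0
      list(y = pre * mask,
           cache = list(body = rb$cache, shortcut = rs$cache, mask = mask))
    },
    stop("unknown layer kind: ", m$kind)
  )
}

nnBackward <- function(m, cache, gy) {
  switch(m$kind,
    conv = {
      r <- conv2d_bwd(cache$x, wAs3d(m$params$w), dim(m$params$w), gy,
                      m$stride, m$pad, m$groups, !is.null(m$params[["b"]]))
      g <- list(w = array(r$gw, dim(m$params$w)))
      if (!is.null(m$params[["b"]])) g$b <- as.numeric(r$gb)
      list(gx = r$gx, grads = g)
    },
    dconv = {
      w <- m$params$w
      r <- dconv2d_bwd(cache$x, wAs3d(w), dim(w), cache$off, gy,
                       m$stride, m$pad, !is.null(m$params[["b"]]))
      ro <- conv2d_bwd(cache$x, wAs3d(m$params$w_off), dim(m$params$w_off),
                       r$goff, m$stride, m$pad, 1L, TRUE)
      g <- list(w = array(r$gw, dim(w)),
                w_off = array(ro$gw, dim(m$params$w_off)),
                b_off = as.numeric(ro$gb))
      if (!is.null(m$params[["b"]])) g$b <- as.numeric(r$gb)
      list(gx = r$gx + ro$gx, grads = g)
    },
    tconv = {
      r <- tconv2d_bwd(cache$x, wAs3d(m$params$w), dim(m$params$w), gy,
                       m$stride, m$pad, !is.null(m$params[["b"]]))
      g <- list(w = array(r$gw, dim(m$params$w)))
      if (!is.null(m$params[["b"]])) g$b <- as.numeric(r$gb)
      list(gx = r$gx, grads = g)
    },
    inorm = {
      d <- cache$d; n <- d[1L] * d[2L]
      gm <- matrix(gy, n, d[3L])
      dgamma <- colSums(gm * cache$xhat)
      dbeta <- colSums(gm)
      dxhat <- sweep(gm, 2L, m$params$gamma, "*")
      mh <- colMeans(dxhat)
      mxh <- colMeans(dxhat * cache$xhat)
      dx <- sweep(sweep(dxhat, 2L, mh, "-") - sweep(cache$xhat, 2L, mxh, "*"),
                  2L, cache$s, "/")
      list(gx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(gx = gy * cache$mask, grads = list()),
    sigmoid = list(gx = gy * cache$y * (1 - cache$y), grads = list()),
    maxpool = list(gx = maxpool_bwd(gy, cache$idx, cache$H, cache$W),
                   grads = list()),
    dense = {
      gy <- as.numeric(gy)
      list(gx = as.numeric(m$params$w %*% gy),
           grads = list(w = outer(cache$x, gy), b = gy))
    },
    gscale = list(gx = gy * m$factor, grads = list()),
    seq = {
      grads <- vector("list", length(m$layers))
      for (i in rev(seq_along(m$layers))) {
        r <- nnBackward(m$layers[[i]], cache[[i]], gy)
        gy <- r$gx
        grads[[i]] <- r$grads
      }
      list(gx = gy, grads = list(layers = grads))
    },
    block = {
      gpre <- gy * cache$mask
      rb <- nnBackward(m$body, cache$body, gpre)
      if (is.null(m$shortcut)) {
        gx <- rb$gx + gpre
        gs <- NULL
      } else {
        rs <- nnBackward(m$shortcut, cache$shortcut, gpre)
        gx <- rb$gx + rs$gx
        gs <- rs$grads
      }
      list(gx = gx, grads = list(body = rb$grads, shortcut = gs))
    },
    stop("unknown layer kind: ", m$kind)
  )
}

## Flatten a module's trainable arrays into a named list ("path" names).
flattenParams <- function(m, prefix = "") {
  out <- list()
  if (!is.null(m$params) && length(m$params)) {
    for (nm in names(m$params))
      out[[paste0(prefix, "params.", nm)]] <- m$params[[nm]]
  }
  if (identical(m$kind, "seq")) {
    for (i in seq_along(m$layers))
      out <- c(out, flattenParams(m$layers[[i]], paste0(prefix, "L", i, ".")))
  } else if (identical(m$kind, "block")) {
    out <- c(out, flattenParams(m$body, paste0(prefix, "body.")))
    if (!is.null(m$shortcut))
      out <- c(out, flattenParams(m$shortcut, paste0(prefix, "sc.")))
  }
  out
}

## Flatten a grads tree (as returned by nnBackward) using the module as guide;
## names align with flattenParams(m).
flattenGrads <- function(m, g, prefix = "") {
  out <- list()
  if (!is.null(m$params) && length(m$params)) {
    for (nm in names(m$params))
      out[[paste0(prefix, "params.", nm)]] <- g[[nm]]
  }
  if (identical(m$kind, "seq")) {
    for (i in seq_along(m$layers))
      out <- c(out, flattenGrads(m$layers[[i]], g$layers[[i]],
                                 paste0(prefix, "L", i, ".")))
  } else if (identical(m$kind, "block")) {
    out <- c(out, flattenGrads(m$body, g$body, paste0(prefix, "body.")))
    if (!is.null(m$shortcut))
      out <- c(out, flattenGrads(m$shortcut, g$shortcut,
                                 paste0(prefix, "sc.")))
  }
  out
}

## Write updated flat params (same names as flattenParams) back into a module.
unflattenParams <- function(m, flat, prefix = "") {
  if (!is.null(m$params) && length(m$params)) {
    for (nm in names(m$params)) {
      key <- paste0(prefix, "params.", nm)
      if (!is.null(flat[[key]])) {
        v <- flat[[key]]
        if (!is.null(dim(m$params[[nm]]))) dim(v) <- dim(m$params[[nm]])
        m$params[[nm]] <- v
      }
    }
  }
  if (identical(m$kind, "seq")) {
    for (i in seq_along(m$layers))
      m$layers[[i]] <- unflattenParams(m$layers[[i]], flat,
                                       paste0(prefix, "L", i, "."))
  } else if (identical(m$kind, "block")) {
    m$body <- unflattenParams(m$body, flat, paste0(prefix, "body."))
    if (!is.null(m$shortcut))
      m$shortcut <- unflattenParams(m$shortcut, flat, paste0(prefix, "sc."))
  }
  m
}

## Elementwise sum of two flat grad lists (x may be NULL).
addFlat <- function(x, y) {
  if (is.null(x)) return(y)
  for (nm in names(y)) {
    x[[nm]] <- if (is.null(x[[nm]])) y[[nm]] else x[[nm]] + y[[nm]]
  }
  x
}

zeroLike <- function(flat) lapply(flat, function(a) a * 0)
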