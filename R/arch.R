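## Backbone geometry. Depth 50/101 follow the canonical bottleneck layout
## (stem 7x7/2 + max-pool, four stages, expansion 4, /32 total downsampling);
## depth 8 is the desk-scale profile: 3x3/2 stem, two bottleneck stages, /8.

archSpec <- function(depth) {
  switch(as.character(depth),
    "8" = list(stemWidth = 16L, stemK = 3L, stemStride = 2L, maxpool = FALSE,
               mids = c(8L, 16L), blocks = c(1L, 1L), strides = c(2L, 2L),
               expansion = 4L, factor = 8L),
    "50" = list(stemWidth = 64L, stemK = 7L, stemStride = 2L, maxpool = TRUE,
                mids = c(64L, 128L, 256L, 512L), blocks = c(3L, 4L, 6L, 3L),
                strides = c(1L, 2L, 2L, 2L), expansion = 4L, factor = 32L),
    "101" = list(stemWidth = 64L, stemK = 7L, stemStride = 2L, maxpool = TRUE,
                 mids = c(64L, 128L, 256L, 512L), blocks = c(3L, 4L, 23L, 3L),
                 strides = c(1L, 2L, 2L, 2L), expansion = 4L, factor = 32L),
    stop("unsupported backbone depth: ", depth)
  )
}

encoderOutChannels <- function(depth) {
  a <- archSpec(depth)
  a$mids[length(a$mids)] * a$expansion
}

## One bottleneck: 1x1 reduce -> 3x3 (grouped or deformable) -> 1x1 expand.
## PGC assigns the pyramid schedule [1, g_mid, mid] to the three convolutions.
bottleneck <- function(cin, mid, stride, pgc = FALSE, deform = FALSE,
                       expansion = 4L, pgcSchedule = NULL) {
  cout <- mid * expansion
  gs <- if (pgc) {
    if (is.null(pgcSchedule)) pgcGroupSchedule(3L, mid) else pgcSchedule
  } else c(1L, 1L, 1L)
  mid3 <- if (deform)
    nnDConv(mid, mid, 3L, stride = stride, pad = 1L, bias = FALSE)
  else
    nnConv(mid, mid, 3L, stride = stride, pad = 1L, groups = gs[2L],
           bias = FALSE)
  body <- nnSeq(
    nnConv(cin, mid, 1L, stride = 1L, pad = 0L, groups = 1L, bias = FALSE),
    nnINorm(mid), nnReLU(),
    mid3,
    nnINorm(mid), nnReLU(),
    nnConv(mid, cout, 1L, stride = 1L, pad = 0L, groups = gs[3L],
           bias = FALSE),
    nnINorm(cout)
  )
  shortcut <- if (stride != 1L || cin != cout)
    nnSeq(nnConv(cin, cout, 1L, stride = stride, pad = 0L, bias = FALSE),
          nnINorm(cout))
  buildBlock <- nnBlock(body, shortcut)
  buildBlock
}

## stream: "texture" (grouped pyramid convolutions) or "shape" (deformable
## 3x3 in the selected deep stages).
buildEncoder <- function(depth, stream = c("texture", "shape"),
                         pgcEnabled = TRUE, pgcSchedule = NULL,
                         deformStages = "deep") {
  stream <- match.arg(stream)
  a <- archSpec(depth)
  nStages <- length(a$mids)
  deformIn <- if (identical(deformStages, "deep")) {
    if (nStages >= 4L) (nStages - 2L):nStages else nStages
  } else if (identical(deformStages, "all")) {
    seq_len(nStages)
  } else as.integer(deformStages)
  layers <- list(
    nnConv(3L, a$stemWidth, a$stemK, stride = a$stemStride,
           pad = a$stemK %/% 2L, bias = FALSE),
    nnINorm(a$stemWidth), nnReLU()
  )
  if (a$maxpool) layers <- c(layers, list(nnMaxPool(3L, 2L, 1L)))
  cin <- a$stemWidth
  for (s in seq_len(nStages)) {
    for (b in seq_len(a$blocks[s])) {
      stride <- if (b == 1L) a$strides[s] else 1L
      layers <- c(layers, list(bottleneck(
        cin, a$mids[s], stride,
        pgc = (stream == "texture") && pgcEnabled,
        deform = (stream == "shape") && (s %in% deformIn),
        expansion = a$expansion, pgcSchedule = pgcSchedule)))
      cin <- a$mids[s] * a$expansion
    }
  }
  do.call(nnSeq, layers)
}

## Decoder: one transposed-conv stage per factor-of-2 of encoder
## downsampling, each followed by a two-conv residual block, then a 1x1 head
## squashed to [0, 1]. No encoder shortcuts.
basicBlock <- function(c) {
  nnBlock(nnSeq(nnConv(c, c, 3L, 1L, 1L, bias = FALSE), nnINorm(c), nnReLU(),
                nnConv(c, c, 3L, 1L, 1L, bias = FALSE), nnINorm(c)),
          NULL)
}

buildDecoder <- function(depth, widths = NULL) {
  a <- archSpec(depth)
  nStages <- as.integer(round(log2(a$factor)))
  cin <- encoderOutChannels(depth)
  if (is.null(widths))
    widths <- pmax(cin %/% 2L^seq_len(nStages), 8L)
  if (length(widths) != nStages)
    stop("decoder needs ", nStages, " stage widths")
  layers <- list()
  for (s in seq_len(nStages)) {
    layers <- c(layers, list(
      nnTConv(cin, widths[s], k = 4L, stride = 2L, pad = 1L, bias = FALSE),
      nnINorm(widths[s]), nnReLU(),
      basicBlock(widths[s])
    ))
    cin <- widths[s]
  }
  layers <- c(layers, list(nnConv(cin, 1L, 1L, 1L, 0L, bias = TRUE),
                           nnSigmoid()))
  do.call(nnSeq, layers)
}
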