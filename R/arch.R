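# Declarative CNN architecture descriptions.  One representation drives
# both the from-scratch trainer and the off-the-shelf-style feature
# extractor replicas: a stack of convolutional layers (each optionally
# followed by max/mean pooling), then a stack of fully connected layers.
# The last FC layer may be a softmax classifier head.  `taps` records which
# FC layers serve as the "prior" (PFCL) and "last" (LFCL) fully-connected
# feature taps.

conv_layer <- function(n, k, stride = 1L, pad = 0L, pool = NULL) {
  if (!is_count(n) || n < 1) stop("n_filters must be a positive integer")
  if (!is_count(k) || k < 1) stop("kernel size must be a positive integer")
  if (!is_count(stride) || stride < 1) stop("stride must be a positive integer")
  if (!is_count(pad) || pad < 0) stop("padding must be a nonnegative integer")
  if (!is.null(pool)) {
    pool$type <- match.arg(pool$type %||% "max", c("max", "mean"))
    pool$size <- pool$size %||% 2L
    pool$stride <- pool$stride %||% pool$size
    if (!is_count(pool$size) || pool$size < 1 ||
        !is_count(pool$stride) || pool$stride < 1)
      stop("pool size and stride must be positive integers")
  }
  list(n = as.integer(n), k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), pool = pool)
}

#' Construct a CNN architecture specification
#'
#' @param input Integer vector `c(m, m, d)`: spatial side and channel depth
#'   of the expected input patch.
#' @param conv_layers List of convolutional layer descriptions, each a list
#'   with `n` (filters), `k` (kernel side), `stride`, `pad`, and optional
#'   `pool = list(type, size, stride)`.
#' @param fc_sizes Integer vector of fully connected layer widths,
#'   including the classifier head when `classifier = TRUE` (its width is
#'   then the number of classes).
#' @param classifier Whether the final FC layer is a softmax classifier
#'   head (from-scratch networks) or the stack is a pure feature extractor.
#' @param taps Named list mapping `PFCL`/`LFCL` to 1-based indices into
#'   `fc_sizes`, or `NA` when the tap does not exist.
#' @param name Display name.
#' @return A `cnn_arch_spec`.  Construction fails, naming the offending
#'   layer, if the spatial dimension chain is inconsistent.
#' @export
arch_spec <- function(input, conv_layers, fc_sizes, classifier = TRUE,
                      taps = NULL, name = "custom") {
  if (length(conv_layers) == 0L) stop("at least one convolutional layer required")
  if (length(fc_sizes) == 0L) stop("at least one fully connected layer required")
  conv_layers <- lapply(conv_layers, function(cl)
    do.call(conv_layer, cl[intersect(names(cl), c("n", "k", "stride", "pad", "pool"))]))
  if (is.null(taps)) {
    nf <- length(fc_sizes)
    taps <- list(PFCL = if (nf >= 2) nf - 1L else NA_integer_, LFCL = nf)
  }
  spec <- structure(list(
    name = name, input = as.integer(input), conv = conv_layers,
    fc = as.integer(fc_sizes), classifier = isTRUE(classifier), taps = taps
  ), class = "cnn_arch_spec")
  arch_geometry(spec)  # validates the chain
  spec
}

# Spatial dimension chain.  Returns, per conv layer, the input side /
# channels, post-conv side and post-pool side; plus the flattened width
# entering the FC stack.
arch_geometry <- function(spec) {
  side <- spec$input[1]
  chan <- spec$input[3]
  layers <- vector("list", length(spec$conv))
  for (i in seq_along(spec$conv)) {
    cl <- spec$conv[[i]]
    out <- (side + 2 * cl$pad - cl$k) %/% cl$stride + 1
    if (side + 2 * cl$pad < cl$k || out < 1)
      stop("conv layer ", i, " (", cl$n, "@", cl$k, "x", cl$k,
           "): kernel larger than its ", side, "-px input")
    pooled <- out
    if (!is.null(cl$pool)) {
      pooled <- (out - cl$pool$size) %/% cl$pool$stride + 1
      if (out < cl$pool$size || pooled < 1)
        stop("conv layer ", i, ": pool window larger than its ",
             out, "-px input")
    }
    layers[[i]] <- list(in_side = side, in_chan = chan,
                        conv_side = out, out_side = pooled, out_chan = cl$n)
    side <- pooled
    chan <- cl$n
  }
  list(layers = layers, flat = side * side * chan,
       final_side = side, final_chan = chan)
}

#' @export
print.cnn_arch_spec <- function(x, ...) {
  geo <- arch_geometry(x)
  cat("CNN architecture '", x$name, "': input ",
      paste(x$input, collapse = "x"), "\n", sep = "")
  for (i in seq_along(x$conv)) {
    cl <- x$conv[[i]]
    g <- geo$layers[[i]]
    cat(sprintf("  conv%-2d %4d @ %dx%d stride %d pad %d -> %dx%d%s\n",
                i, cl$n, cl$k, cl$k, cl$stride, cl$pad,
                g$conv_side, g$conv_side,
                if (!is.null(cl$pool))
                  sprintf(" -> %s-pool %d/%d -> %dx%d", cl$pool$type,
                          cl$pool$size, cl$pool$stride, g$out_side, g$out_side)
                else ""))
  }
  cat("  fc:", paste(x$fc, collapse = " -> "),
      if (x$classifier) "(softmax head)" else "(feature stack)", "\n")
  cat("  taps: PFCL =", x$taps$PFCL, " LFCL =", x$taps$LFCL, "\n")
  invisible(x)
}

#' From-scratch CNN architecture presets
#'
#' Five small architectures for 128 x 128 x 3 patches (`CNN-01` ...
#' `CNN-05`) and one AlexNet-style network for 227 x 227 x 3 subimages
#' (`ARCH-227`).  Only the filter counts/sizes and the hidden FC width are
#' intrinsic to each preset; the remaining geometry is fixed here as:
#' first conv stride 3 (stride 4 for `ARCH-227`), 2x2 max pooling of
#' stride 2 after the first two conv stages (stages 1, 2 and 5 for
#' `ARCH-227`), all other convolutions valid with stride 1, and ReLU after
#' every layer except the softmax head -- the smallest set of choices that
#' keeps every preset's spatial chain positive with a near-global final
#' convolution.
#'
#' `CNN-05` is conv 48@11x11, conv 72@5x5, conv 1024@6x6, FC 1024, then a
#' 2-way softmax head.
#'
#' @param name One of `"CNN-01"`..`"CNN-05"`, `"ARCH-227"`.
#' @param n_classes Number of output classes for the softmax head.
#' @return A `cnn_arch_spec`.
#' @export
scratch_arch <- function(name = c("CNN-05", "CNN-01", "CNN-02", "CNN-03",
                                  "CNN-04", "ARCH-227"),
                         n_classes = 2L) {
  name <- match.arg(name)
  p2 <- list(type = "max", size = 2L, stride = 2L)
  small <- function(f1, k1, f2, k2, f3, k3, fc)
    arch_spec(c(128L, 128L, 3L),
              list(list(n = f1, k = k1, stride = 3L, pool = p2),
                   list(n = f2, k = k2, pool = p2),
                   list(n = f3, k = k3)),
              c(fc, n_classes), classifier = TRUE, name = name)
  switch(name,
    "CNN-01" = small(48L, 7L, 72L, 4L, 512L, 5L, 512L),
    "CNN-02" = small(48L, 11L, 72L, 5L, 512L, 6L, 512L),
    "CNN-03" = small(24L, 11L, 48L, 5L, 1024L, 6L, 1024L),
    "CNN-04" = small(24L, 11L, 72L, 4L, 2048L, 5L, 2048L),
    "CNN-05" = small(48L, 11L, 72L, 5L, 1024L, 6L, 1024L),
    "ARCH-227" = arch_spec(
      c(227L, 227L, 3L),
      list(list(n = 96L, k = 11L, stride = 4L, pool = p2),
           list(n = 256L, k = 5L, pad = 2L, pool = p2),
           list(n = 384L, k = 3L, pad = 1L),
           list(n = 384L, k = 3L, pad = 1L),
           list(n = 256L, k = 3L, pad = 1L, pool = p2),
           list(n = 384L, k = 3L, pad = 1L),
           list(n = 384L, k = 3L, pad = 1L),
           list(n = 4096L, k = 6L)),
      c(4096L, n_classes), classifier = TRUE, name = name))
}

#' Off-the-shelf CNN architecture replicas
#'
#' Shape replicas of the published ImageNet architectures used as feature
#' extractors: all take 224 x 224 x 3 input, and their feature taps are the
#' two fully connected layers before the 1000-way ImageNet head (4096 wide;
#' for GoogleLeNet the single 1024-wide pooled feature vector serves as
#' both taps).  The replicas reproduce each network's weight-layer
#' structure and tap widths; convolutional internals of the inception
#' modules are simplified to a sequential stack of equivalent spatial
#' shape.  Weights are random at construction; externally trained weights
#' can be installed with [load_external_weights()].
#'
#' @param name One of `"VGG-VD16"`, `"VGG-VD19"`, `"CNN-F"`, `"CNN-M"`,
#'   `"CNN-S"`, `"AlexNet"`, `"GoogleLeNet"`.
#' @param mcn Flag marking the MatConvNet re-trained variant of the same
#'   architecture (identical shapes; recorded in the name).
#' @return A `cnn_arch_spec` whose PFCL tap is 4096 wide (1024 for
#'   GoogleLeNet).
#' @export
offshelf_arch <- function(name = c("VGG-VD16", "VGG-VD19", "CNN-F", "CNN-M",
                                   "CNN-S", "AlexNet", "GoogleLeNet"),
                          mcn = FALSE) {
  name <- match.arg(name)
  p2 <- list(type = "max", size = 2L, stride = 2L)
  c3 <- function(n, pool = NULL) list(n = n, k = 3L, pad = 1L, pool = pool)
  vgg_block <- function(n, reps, pool_last = TRUE) {
    lapply(seq_len(reps), function(i)
      c3(n, pool = if (pool_last && i == reps) p2 else NULL))
  }
  label <- if (mcn) paste(name, "MCN") else name
  spec <- switch(name,
    "VGG-VD16" = arch_spec(c(224L, 224L, 3L),
      c(vgg_block(64L, 2), vgg_block(128L, 2), vgg_block(256L, 3),
        vgg_block(512L, 3), vgg_block(512L, 3)),
      c(4096L, 4096L, 1000L), classifier = TRUE,
      taps = list(PFCL = 1L, LFCL = 2L), name = label),
    "VGG-VD19" = arch_spec(c(224L, 224L, 3L),
      c(vgg_block(64L, 2), vgg_block(128L, 2), vgg_block(256L, 4),
        vgg_block(512L, 4), vgg_block(512L, 4)),
      c(4096L, 4096L, 1000L), classifier = TRUE,
      taps = list(PFCL = 1L, LFCL = 2L), name = label),
    "CNN-F" = arch_spec(c(224L, 224L, 3L),
      list(list(n = 64L, k = 11L, stride = 4L, pool = p2),
           list(n = 256L, k = 5L, pad = 2L, pool = p2),
           c3(256L), c3(256L), c3(256L, pool = p2)),
      c(4096L, 4096L, 1000L), classifier = TRUE,
      taps = list(PFCL = 1L, LFCL = 2L), name = label),
    "CNN-M" = arch_spec(c(224L, 224L, 3L),
      list(list(n = 96L, k = 7L, stride = 2L, pool = p2),
           list(n = 256L, k = 5L, stride = 2L, pad = 1L, pool = p2),
           c3(512L), c3(512L), c3(512L, pool = p2)),
      c(4096L, 4096L, 1000L), classifier = TRUE,
      taps = list(PFCL = 1L, LFCL = 2L), name = label),
    "CNN-S" = arch_spec(c(224L, 224L, 3L),
      list(list(n = 96L, k = 7L, stride = 2L, pool = p2),
           list(n = 256L, k = 5L, pad = 1L, pool = p2),
           c3(512L), c3(512L),
           c3(512L, pool = list(type = "max", size = 4L, stride = 4L))),
      c(4096L, 4096L, 1000L), classifier = TRUE,
      taps = list(PFCL = 1L, LFCL = 2L), name = label),
    "AlexNet" = arch_spec(c(224L, 224L, 3L),
      list(list(n = 96L, k = 11L, stride = 4L, pool = p2),
           list(n = 256L, k = 5L, pad = 2L, pool = p2),
           c3(384L), c3(384L), c3(256L, pool = p2)),
      c(4096L, 4096L, 1000L), classifier = TRUE,
      taps = list(PFCL = 1L, LFCL = 2L), name = label),
    "GoogleLeNet" = arch_spec(c(224L, 224L, 3L),
      list(list(n = 64L, k = 7L, stride = 2L, pad = 3L, pool = p2),
           list(n = 192L, k = 3L, pad = 1L, pool = p2),
           c3(256L, pool = p2), c3(480L), c3(512L, pool = p2),
           c3(832L),
           c3(1024L, pool = list(type = "mean", size = 7L, stride = 7L))),
      c(1024L), classifier = FALSE,
      taps = list(PFCL = 1L, LFCL = 1L), name = label))
  spec
}
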