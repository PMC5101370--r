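# Classical texture descriptors (multiscale block LBP, Gabor-wavelet
# Weibull), off-the-shelf CNN feature taps, and feature-level fusion.

block_means <- function(gray, b) {
  # mean of every b x b block by integral image; output indexed by the
  # block's top-left pixel
  H <- nrow(gray); W <- ncol(gray)
  S <- matrix(0, H + 1, W + 1)
  S[-1, -1] <- apply(apply(gray, 2, cumsum), 1, cumsum) |> t()
  i <- seq_len(H - b + 1); j <- seq_len(W - b + 1)
  (S[i + b, j + b] - S[i, j + b] - S[i + b, j] + S[i, j]) / (b * b)
}

#' Multiscale block local binary pattern histogram
#'
#' LBP codes computed on block means instead of single pixels: at every
#' valid position the mean of each of the 8 neighbouring `b x b` blocks is
#' compared (>= counts as 1, so a constant image gives code 255) with the
#' central block mean, producing an 8-bit code.  Codes are histogrammed
#' over 256 bins and normalized to sum 1; histograms from all requested
#' scales are concatenated.  Bit order runs clockwise from the top-left
#' neighbour.
#'
#' @param img A `labeled_image`, an H x W x 3 array, or a grayscale matrix.
#'   Colour inputs are converted to luminance (0.299/0.587/0.114).
#' @param block_scales Integer vector of block side lengths in px.
#' @return Numeric feature vector of length `256 * length(block_scales)`
#'   with a `provenance` attribute.
#' @export
mb_lbp_features <- function(img, block_scales = c(1L, 3L, 5L)) {
  px <- if (inherits(img, "labeled_image")) img$pixels else img
  gray <- to_gray(px)
  H <- nrow(gray); W <- ncol(gray)
  # clockwise from top-left: bit k has weight 2^k
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  out <- numeric(0)
  for (b in block_scales) {
    if (3 * b > min(H, W))
      stop("block scale ", b, " too large for a ", H, "x", W, " image")
    M <- block_means(gray, b)
    # valid centre top-lefts: all 8 neighbour blocks must fit
    ci <- (b + 1):(H - 2 * b + 1)
    cj <- (b + 1):(W - 2 * b + 1)
    centre <- M[ci, cj, drop = FALSE]
    code <- matrix(0, length(ci), length(cj))
    for (k in 1:8) {
      nb <- M[ci + offs[k, 1] * b, cj + offs[k, 2] * b, drop = FALSE]
      # >= with a tolerance absorbing integral-image rounding, so exact
      # ties (constant regions) count as 1
      code <- code + 2^(k - 1) * (nb >= centre - 1e-10)
    }
    h <- tabulate(as.integer(code) + 1L, nbins = 256L)
    out <- c(out, h / sum(h))
  }
  structure(out, provenance = list(extractor = "mb_lbp",
                                   block_scales = block_scales))
}

# Complex Gabor kernel pair (real/imaginary) on a symmetric odd grid.
# Orientation theta + 90 degrees equals the 90-degree rotation of the
# theta kernel, which makes orientation blocks permute exactly under image
# rotation.
gabor_kernel <- function(lambda, theta, sigma, gamma, half) {
  g <- seq(-half, half)
  x <- matrix(g, 2 * half + 1, 2 * half + 1, byrow = TRUE)  # column coord
  y <- matrix(g, 2 * half + 1, 2 * half + 1)                # row coord
  xp <- x * cos(theta) + y * sin(theta)
  yp <- -x * sin(theta) + y * cos(theta)
  env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
  list(re = env * cos(2 * pi * xp / lambda),
       im = env * sin(2 * pi * xp / lambda))
}

#' Two-parameter Weibull fit by maximum likelihood
#'
#' Solves the profile likelihood equation for the shape parameter by
#' safeguarded Newton iteration (tolerance 1e-8), then recovers the scale
#' parameter in closed form.  Requires strictly positive observations.
#'
#' @param x Positive numeric observations.
#' @param tol Convergence tolerance on the shape update.
#' @return Named vector `c(shape, scale)`.
#' @export
weibull_fit_mle <- function(x, tol = 1e-8) {
  x <- x[x > 0]
  if (length(x) < 2L) stop("need at least two positive observations")
  lx <- log(x)
  mlx <- mean(lx)
  gfun <- function(k) {
    xk <- x^k
    sum(xk * lx) / sum(xk) - 1 / k - mlx
  }
  k <- 1
  for (it in 1:100) {
    xk <- x^k
    s0 <- sum(xk); s1 <- sum(xk * lx); s2 <- sum(xk * lx^2)
    g <- s1 / s0 - 1 / k - mlx
    gp <- (s2 * s0 - s1^2) / s0^2 + 1 / k^2
    step <- g / gp
    knew <- k - step
    if (!is.finite(knew) || knew <= 0) knew <- k / 2
    if (abs(knew - k) < tol) { k <- knew; break }
    k <- knew
  }
  if (!is.finite(k) || k <= 0)
    k <- uniroot(gfun, c(1e-3, 100), extendInt = "yes", tol = tol)$root
  scale <- mean(x^k)^(1 / k)
  c(shape = k, scale = scale)
}

#' Gabor-wavelet Weibull texture descriptor
#'
#' Filters the luminance image with a bank of complex Gabor wavelets
#' (log-spaced wavelengths, evenly spaced orientations over 180 degrees;
#' circular FFT convolution) and fits a two-parameter Weibull distribution
#' to the magnitude responses of every (scale, orientation) subband by
#' maximum likelihood.  The feature vector concatenates the (shape, scale)
#' pairs, scale-major, giving length `2 * n_scales * n_orientations`.
#'
#' @param img A `labeled_image`, H x W x 3 array, or grayscale matrix.
#' @param n_scales Number of wavelengths (4, 8, 16, ... px).
#' @param n_orientations Number of orientations in `[0, 180)` degrees.
#' @param gamma Spatial aspect ratio of the Gaussian envelope.
#' @return Numeric feature vector with a `provenance` attribute.  An
#'   all-zero subband (e.g. a constant image) raises an error naming the
#'   (scale, orientation) pair.
#' @export
gwt_weibull_features <- function(img, n_scales = 4L, n_orientations = 6L,
                                 gamma = 0.5) {
  px <- if (inherits(img, "labeled_image")) img$pixels else img
  gray <- to_gray(px)
  H <- nrow(gray); W <- ncol(gray)
  out <- numeric(0)
  for (s in seq_len(n_scales)) {
    lambda <- 4 * 2^(s - 1)
    sigma <- 0.56 * lambda
    half <- min(ceiling(3 * sigma), (min(H, W) - 1) %/% 2)
    if (half < 1) stop("image smaller than the smallest Gabor filter")
    for (o in seq_len(n_orientations)) {
      theta <- (o - 1) * pi / n_orientations
      kern <- gabor_kernel(lambda, theta, sigma, gamma, half)
      re <- EBImage::filter2(gray, kern$re, boundary = "circular")
      im <- EBImage::filter2(gray, kern$im, boundary = "circular")
      mag <- sqrt(re^2 + im^2)
      if (max(mag) < 1e-10)
        stop("degenerate (all-zero) subband at scale ", s,
             ", orientation ", o)
      out <- c(out, weibull_fit_mle(as.numeric(mag)))
    }
  }
  structure(as.numeric(out),
            provenance = list(extractor = "gwt_weibull",
                              n_scales = n_scales,
                              n_orientations = n_orientations))
}

#' Extract an off-the-shelf CNN feature vector from an image
#'
#' Feeds a full image (already brought to the network's 224 x 224 x 3
#' input size with [resize_bicubic()]) through an off-the-shelf
#' architecture replica and returns the activation vector at the requested
#' fully connected tap (4096-dimensional for most networks, 1024 for
#' GoogleLeNet).
#'
#' @param model A `scratch_cnn` built from [offshelf_arch()] (random or
#'   externally loaded weights).
#' @param img A `labeled_image` or array matching the model input size.
#' @param tap `"PFCL"` or `"LFCL"`.
#' @return Numeric feature vector with a `provenance` attribute.
#' @export
extract_offshelf_features <- function(model, img, tap = c("PFCL", "LFCL")) {
  tap <- match.arg(tap)
  px <- if (inherits(img, "labeled_image")) img$pixels else img
  extract_layer_vector(model, px, tap)
}

#' Feature-level fusion by concatenation
#'
#' Concatenates feature vectors in the given order, recording block
#' boundaries and provenance so that fused columns remain traceable to
#' their extractor.
#'
#' @param vectors Non-empty list of numeric feature vectors (as returned
#'   by the extractors).
#' @return Numeric vector of the summed length with a `blocks` attribute
#'   (data frame: name, start, end).
#' @export
fuse_features <- function(vectors) {
  if (!is.list(vectors) || length(vectors) == 0L)
    stop("fuse_features needs a non-empty list of vectors")
  lens <- vapply(vectors, length, 0L)
  names_ <- vapply(seq_along(vectors), function(i) {
    pr <- attr(vectors[[i]], "provenance")
    pr$extractor %||% paste0("block", i)
  }, "")
  ends <- cumsum(lens)
  blocks <- data.frame(name = names_, start = ends - lens + 1L, end = ends,
                       stringsAsFactors = FALSE)
  structure(unlist(lapply(vectors, as.numeric), use.names = FALSE),
            blocks = blocks)
}
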