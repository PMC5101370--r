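# Bicubic resampling (Keys kernel, a = -0.5), implemented as separable
# sparse row/column weight matrices.  Out-of-range taps are linearly
# extrapolated from the two border pixels, which keeps the operator exact
# on constant and linear ramps up to the image edge; resizing to the same
# size is the identity.

keys_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# T_ x S weight matrix mapping S source samples to T_ target samples with
# centre-aligned coordinates.  Out-of-range taps j < 1 are extrapolated as
# x[1] + (1 - j) * (x[1] - x[2]); j > S as x[S] + (j - S) * (x[S] - x[S-1]).
resize_vector_weights <- function(S, T_) {
  W <- matrix(0, T_, S)
  scale <- S / T_
  for (i in seq_len(T_)) {
    u <- (i - 0.5) * scale + 0.5
    base <- floor(u)
    t <- u - base
    for (d in -1:2) {
      w <- keys_kernel(t - d)
      if (w == 0) next
      j <- base + d
      if (j < 1) {
        W[i, 1] <- W[i, 1] + w * (1 + (1 - j))
        W[i, 2] <- W[i, 2] - w * (1 - j)
      } else if (j > S) {
        W[i, S] <- W[i, S] + w * (1 + (j - S))
        W[i, S - 1] <- W[i, S - 1] - w * (j - S)
      } else {
        W[i, j] <- W[i, j] + w
      }
    }
  }
  W
}

resize_matrix_bicubic <- function(mat, target) {
  Wr <- resize_vector_weights(nrow(mat), target)
  Wc <- resize_vector_weights(ncol(mat), target)
  Wr %*% mat %*% t(Wc)
}

#' Bicubic image resizing
#'
#' Resamples a square RGB image to `target` x `target` pixels with the
#' bicubic (Keys, a = -0.5) kernel, the interpolation conventionally used
#' to bring images to a CNN's required input size (e.g. 256 to 224).
#' Values are clipped back to `[0, 1]`.
#'
#' @param img A `labeled_image` or an H x W x 3 array in `[0, 1]`.
#' @param target Target side length in pixels (>= 4).
#' @return Same type as the input, resized to `target` x `target` x 3.
#' @export
resize_bicubic <- function(img, target) {
  if (!is_count(target) || target < 4) stop("target must be an integer >= 4")
  px <- if (inherits(img, "labeled_image")) img$pixels else img
  d <- dim(px)
  out <- array(0, c(target, target, d[3]))
  Wr <- resize_vector_weights(d[1], target)
  Wc <- resize_vector_weights(d[2], target)
  for (ch in seq_len(d[3]))
    out[, , ch] <- clamp01(Wr %*% px[, , ch] %*% t(Wc))
  if (inherits(img, "labeled_image")) {
    img$pixels <- out
    img
  } else out
}
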