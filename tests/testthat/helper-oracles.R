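# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths.

# Direct-convolution CNN forward pass in plain R loops (double precision).
# Mirrors the layer semantics (valid/padded conv, ReLU, max/mean pool,
# FC stack, softmax) without sharing any code with the package.
naive_cnn_forward <- function(model, x, upto_fc = length(model$fc),
                              softmax = FALSE) {
  conv_one <- function(img, W, b, k, stride, pad) {
    H <- dim(img)[1]; C <- dim(img)[3]
    nf <- nrow(W)
    Ho <- (H + 2 * pad - k) %/% stride + 1
    padded <- array(0, c(H + 2 * pad, H + 2 * pad, C))
    padded[pad + seq_len(H), pad + seq_len(H), ] <- img
    out <- array(0, c(Ho, Ho, nf))
    for (f in seq_len(nf)) {
      wf <- array(W[f, ], c(k, k, C))
      for (i in seq_len(Ho)) for (j in seq_len(Ho)) {
        patch <- padded[(i - 1) * stride + seq_len(k),
                        (j - 1) * stride + seq_len(k), , drop = FALSE]
        out[i, j, f] <- sum(patch * wf) + b[f]
      }
    }
    out
  }
  pool_one <- function(a, size, stride, type) {
    Ho <- (dim(a)[1] - size) %/% stride + 1
    out <- array(0, c(Ho, Ho, dim(a)[3]))
    f <- if (type == "max") max else mean
    for (c_ in seq_len(dim(a)[3]))
      for (i in seq_len(Ho)) for (j in seq_len(Ho))
        out[i, j, c_] <- f(a[(i - 1) * stride + seq_len(size),
                             (j - 1) * stride + seq_len(size), c_])
    out
  }
  a <- x
  for (l in seq_along(model$conv)) {
    cl <- model$arch$conv[[l]]
    z <- conv_one(a, model$conv[[l]]$W, model$conv[[l]]$b,
                  cl$k, cl$stride, cl$pad)
    a <- pmax(z, 0)
    if (!is.null(cl$pool))
      a <- pool_one(a, cl$pool$size, cl$pool$stride, cl$pool$type)
  }
  h <- as.numeric(a)
  for (i in seq_len(upto_fc)) {
    z <- as.numeric(model$fc[[i]]$W %*% h + model$fc[[i]]$b)
    head <- model$arch$classifier && i == length(model$fc)
    h <- if (head) z else pmax(z, 0)
  }
  if (softmax) { e <- exp(h - max(h)); h <- e / sum(e) }
  h
}

# Brute-force blob statistic: segment dark blobs by thresholding, label
# connected components (EBImage), and average each component's elongation
# (sqrt of the eigenvalue ratio of its pixel scatter).  Used to verify
# that the generator's class-separating cue is recoverable from rendered
# pixels without knowledge of the generator's internals.
blob_elongation_stat <- function(px) {
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  bw <- g < (mean(g) - 0.5 * sd(g))
  lab <- EBImage::bwlabel(bw)
  n <- max(lab)
  if (n < 1) return(NA_real_)
  el <- c()
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < 6) next
    ev <- eigen(cov(idx), symmetric = TRUE, only.values = TRUE)$values
    if (ev[2] <= 0) next
    el <- c(el, sqrt(ev[1] / ev[2]))
  }
  if (!length(el)) NA_real_ else mean(el)
}

# Exact two-sided McNemar p-value by combinatorial enumeration of all
# 2^n equally likely discordance outcomes (n = n01 + n10 <= ~20).
mcnemar_enum_p <- function(n01, n10) {
  n <- n01 + n10
  if (n == 0) return(1)
  kmin <- min(n01, n10)
  lower <- sum(choose(n, 0:kmin)) / 2^n
  min(1, 2 * lower)
}

# Hand enumeration of MB-LBP codes: naive block means by explicit loops.
naive_mb_lbp_hist <- function(gray, b) {
  H <- nrow(gray); W <- ncol(gray)
  bmean <- function(i, j) mean(gray[i:(i + b - 1), j:(j + b - 1)])
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  codes <- c()
  for (i in (b + 1):(H - 2 * b + 1)) {
    for (j in (b + 1):(W - 2 * b + 1)) {
      cm <- bmean(i, j)
      code <- 0
      for (k in 1:8) {
        nb <- bmean(i + offs[k, 1] * b, j + offs[k, 2] * b)
        if (nb >= cm) code <- code + 2^(k - 1)
      }
      codes <- c(codes, code)
    }
  }
  h <- tabulate(codes + 1L, nbins = 256L)
  h / sum(h)
}
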