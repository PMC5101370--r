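# From-scratch CNN: seeded initialization, im2col-based forward/backward
# (C++ primitives), momentum-SGD training with softmax cross-entropy,
# image-level classification by majority vote over patch decisions, and
# internal layer taps for CNN + SVM variants.

#' Training configuration for from-scratch CNNs
#'
#' Momentum SGD with a step learning-rate schedule.  Defaults: 30 epochs,
#' batch 64, learning rate 0.01 decayed by 10x after two thirds of the
#' epochs, momentum 0.9, weight decay 5e-4.  The seed fixes weight
#' initialization and batch order, making training bit-reproducible.
#'
#' @param epochs Number of passes over the training patches.
#' @param batch_size Minibatch size.
#' @param lr Initial learning rate.
#' @param lr_decay Multiplicative decay factor applied at `lr_step`.
#' @param lr_step Epoch fraction (0-1] at which the decay triggers.
#' @param momentum Momentum coefficient (SGD only).
#' @param weight_decay L2 penalty coefficient.
#' @param clip Per-tensor L2 gradient-norm ceiling; minibatch gradients
#'   with a larger norm are rescaled to it, damping the early-epoch loss
#'   spikes that can kill ReLU units on small patch sets.  `Inf` disables
#'   clipping.
#' @param optimizer `"sgd"` (momentum SGD, the default) or `"adam"`
#'   (per-parameter adaptive steps; converges in far fewer epochs on small
#'   patch sets, so it is what the scaled-down validation experiments use
#'   with `lr = 1e-3`).
#' @param seed Integer seed.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, batch_size = 64L, lr = 0.01,
                         lr_decay = 0.1, lr_step = 2 / 3, momentum = 0.9,
                         weight_decay = 5e-4, clip = 5,
                         optimizer = c("sgd", "adam"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(is_count(epochs), is_count(batch_size), batch_size >= 1,
            lr > 0, momentum >= 0, weight_decay >= 0, clip > 0,
            lr_step > 0, lr_step <= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay = lr_decay, lr_step = lr_step,
                 momentum = momentum, weight_decay = weight_decay,
                 clip = clip, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "train_config")
}

clip_grad <- function(g, clip) {
  if (!is.finite(clip)) return(g)
  gn <- sqrt(sum(g * g))
  if (gn > clip) g * (clip / gn) else g
}

#' Build a (still untrained) CNN from an architecture spec
#'
#' Allocates scaled-Gaussian (He) initialized weights for every layer,
#' deterministically given the seed.
#'
#' @param spec A `cnn_arch_spec` (see [scratch_arch()], [offshelf_arch()],
#'   [arch_spec()]).
#' @param seed Integer seed for the initialization.
#' @return A `scratch_cnn` model object.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_arch_spec"))
  geo <- arch_geometry(spec)
  with_seed(seed, {
    conv_w <- vector("list", length(spec$conv))
    for (i in seq_along(spec$conv)) {
      cl <- spec$conv[[i]]
      fan_in <- cl$k * cl$k * geo$layers[[i]]$in_chan
      conv_w[[i]] <- list(
        W = matrix(rnorm(cl$n * fan_in, 0, sqrt(2 / fan_in)), cl$n, fan_in),
        b = numeric(cl$n))
    }
    fc_w <- vector("list", length(spec$fc))
    prev <- geo$flat
    for (i in seq_along(spec$fc)) {
      fc_w[[i]] <- list(
        W = matrix(rnorm(spec$fc[i] * prev, 0, sqrt(2 / prev)),
                   spec$fc[i], prev),
        b = numeric(spec$fc[i]))
      prev <- spec$fc[i]
    }
    structure(list(arch = spec, conv = conv_w, fc = fc_w,
                   trained = FALSE, loss_history = numeric(0)),
              class = "scratch_cnn")
  })
}

#' Count trainable parameters
#'
#' @param model A `scratch_cnn`.
#' @return Total number of trainable scalars (weights + biases).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "scratch_cnn"))
  sum(vapply(c(model$conv, model$fc),
             function(l) length(l$W) + length(l$b), 0))
}

#' @export
print.scratch_cnn <- function(x, ...) {
  cat(if (x$trained) "Trained" else "Untrained", "CNN (",
      format(count_parameters(x), big.mark = ","), "parameters )\n")
  print(x$arch)
  if (length(x$loss_history))
    cat("  final training loss:",
        signif(x$loss_history[length(x$loss_history)], 4), "\n")
  invisible(x)
}

#' @export
plot.scratch_cnn <- function(x, ...) {
  if (!length(x$loss_history)) stop("model has no loss history")
  plot(seq_along(x$loss_history) - 1, x$loss_history, type = "b",
       xlab = "epoch", ylab = "training loss",
       main = paste("Training loss,", x$arch$name), ...)
  invisible(x)
}

# Forward through the conv stack.  x: (H, W, C, N).  Returns the flattened
# matrix (flat x N) plus per-layer caches when `keep = TRUE`.
conv_stack_forward <- function(model, x, keep = FALSE) {
  caches <- if (keep) vector("list", length(model$conv)) else NULL
  for (i in seq_along(model$conv)) {
    cl <- model$arch$conv[[i]]
    z <- .conv_fwd(x, dim(x), model$conv[[i]]$W, model$conv[[i]]$b,
                   cl$k, cl$stride, cl$pad)
    a <- z * (z > 0)
    if (is.null(cl$pool)) {
      out <- a; idx <- NULL
    } else {
      pf <- .pool_fwd(a, dim(a), cl$pool$size, cl$pool$stride,
                      cl$pool$type == "max")
      out <- pf$y; idx <- pf$idx
    }
    if (keep) caches[[i]] <- list(x = x, z = z, a_dim = dim(a),
                                  out_dim = dim(out), idx = idx)
    x <- out
  }
  n <- dim(x)[4]
  list(flat = matrix(x, ncol = n), caches = caches)
}

# Forward through FC layers 1..upto (defaults to all).  ReLU after every
# layer except a classifier head's output.  h: (flat x N).
fc_stack_forward <- function(model, h, upto = length(model$fc),
                             keep = FALSE) {
  caches <- if (keep) vector("list", upto) else NULL
  for (i in seq_len(upto)) {
    z <- model$fc[[i]]$W %*% h + model$fc[[i]]$b
    is_head <- model$arch$classifier && i == length(model$fc)
    a <- if (is_head) z else z * (z > 0)
    if (keep) caches[[i]] <- list(x = h, z = z, head = is_head)
    h <- a
  }
  list(out = h, caches = caches)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Full forward to class probabilities.  x: (H, W, C, N) -> (n_classes x N).
cnn_forward_probs <- function(model, x) {
  flat <- conv_stack_forward(model, x)$flat
  logits <- fc_stack_forward(model, flat)$out
  softmax_cols(logits)
}

check_patch_dim <- function(model, x) {
  d <- dim(x)
  inp <- model$arch$input
  if (length(d) == 3L) {
    x <- array(x, c(d, 1L)); d <- dim(x)
  }
  if (length(d) != 4L || d[1] != inp[1] || d[2] != inp[2] || d[3] != inp[3])
    stop("patch size ", paste(d[1:3], collapse = "x"),
         " does not match the model input ", paste(inp, collapse = "x"))
  x
}

#' Class probabilities for one normalized patch
#'
#' Runs the patch through the network and returns the softmax output: two
#' (or `n_classes`) nonnegative probabilities summing to one.  The model's
#' preprocessing contract expects the patch already normalized with
#' [normalize_patch()].
#'
#' @param model A `scratch_cnn` with a classifier head.
#' @param patch A P x P x 3 array matching the model input.
#' @return Numeric vector of class probabilities (healthy, abnormal).
#' @export
predict_patch <- function(model, patch) {
  stopifnot(inherits(model, "scratch_cnn"))
  if (!model$arch$classifier) stop("model has no classifier head")
  x <- check_patch_dim(model, patch)
  p <- cnn_forward_probs(model, x)[, 1]
  names(p) <- if (length(p) == 2L) c("healthy", "abnormal") else NULL
  p
}

#' @export
predict.scratch_cnn <- function(object, newdata, type = c("prob", "class"),
                                batch = 32L, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "patch_set")) newdata$pixels else newdata
  x <- check_patch_dim(object, x)
  n <- dim(x)[4]
  probs <- matrix(0, length(object$fc[[length(object$fc)]]$b), n)
  for (s in seq(1L, n, by = batch)) {
    e <- min(n, s + batch - 1L)
    probs[, s:e] <- cnn_forward_probs(object, x[, , , s:e, drop = FALSE])
  }
  if (type == "prob") t(probs)
  else as.integer(probs[2, ] >= probs[1, ])  # patch-level tie -> abnormal
}

#' Train a from-scratch CNN on labeled patches
#'
#' Minimizes softmax cross-entropy by momentum SGD.  Patches are
#' normalized internally per the model's preprocessing contract.  Training
#' is deterministic given the configuration seed; the returned model
#' carries its per-epoch loss history, with entry 0 the loss of the
#' initialized network before any update.
#'
#' @param model An (untrained or trained) `scratch_cnn` with classifier head.
#' @param patches A `patch_set` or a P x P x 3 x N array matching the model
#'   input.
#' @param labels Integer vector (0 = healthy, 1 = abnormal), one per patch.
#'   Taken from the `patch_set` metadata when omitted.
#' @param config A [train_config()].
#' @return The trained `scratch_cnn` (with `loss_history`).
#' @export
train_cnn <- function(model, patches, labels = NULL,
                      config = train_config()) {
  stopifnot(inherits(model, "scratch_cnn"), inherits(config, "train_config"))
  if (!model$arch$classifier) stop("model has no classifier head")
  if (inherits(patches, "patch_set")) {
    labels <- labels %||% patches$meta$label
    patches <- patches$pixels
  }
  x <- check_patch_dim(model, patches)
  n <- dim(x)[4]
  labels <- as.integer(labels)
  if (length(labels) != n) stop("one label per patch required")
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  x <- normalize_batch(x)
  n_cls <- model$arch$fc[length(model$arch$fc)]
  y1 <- labels + 1L                      # 1-based class index

  # private weight copies (updates happen in place) + optimizer state
  model$conv <- lapply(model$conv, function(l)
    list(W = l$W + 0, b = l$b + 0))
  model$fc <- lapply(model$fc, function(l)
    list(W = l$W + 0, b = l$b + 0))
  zero_like <- function(part) lapply(part, function(l)
    list(W = l$W * 0, b = l$b * 0))
  st1 <- list(conv = zero_like(model$conv), fc = zero_like(model$fc))
  st2 <- if (config$optimizer == "adam")
    list(conv = zero_like(model$conv), fc = zero_like(model$fc)) else NULL
  step_t <- 0L

  batch_loss <- function(probs, y1b)
    -mean(log(pmax(probs[cbind(y1b, seq_along(y1b))], 1e-12)))

  full_loss <- function(m) {
    tot <- 0
    for (s in seq(1L, n, by = 64L)) {
      e <- min(n, s + 63L)
      pr <- cnn_forward_probs(m, x[, , , s:e, drop = FALSE])
      tot <- tot + batch_loss(pr, y1[s:e]) * (e - s + 1L)
    }
    tot / n
  }

  model$loss_history <- full_loss(model)
  if (config$epochs == 0L) { model$trained <- TRUE; return(model) }

  with_seed(config$seed, {
    decay_at <- ceiling(config$epochs * config$lr_step)
    lr <- config$lr
    for (ep in seq_len(config$epochs)) {
      if (ep == decay_at + 1L) lr <- lr * config$lr_decay
      ord <- sample.int(n)
      ep_loss <- 0
      for (s in seq(1L, n, by = config$batch_size)) {
        idx <- ord[s:min(n, s + config$batch_size - 1L)]
        xb <- x[, , , idx, drop = FALSE]
        nb <- length(idx)

        step_t <- step_t + 1L
        upd <- function(part, i, slot, g) {
          g <- clip_grad(g, config$clip)
          wd <- if (slot == "W") config$weight_decay else 0
          if (config$optimizer == "adam") {
            .adam_step(model[[part]][[i]][[slot]], st1[[part]][[i]][[slot]],
                       st2[[part]][[i]][[slot]], g, lr, 0.9, 0.999, 1e-8,
                       wd, step_t)
          } else {
            .sgd_step(model[[part]][[i]][[slot]], st1[[part]][[i]][[slot]],
                      g, lr, config$momentum, wd)
          }
        }

        cs <- conv_stack_forward(model, xb, keep = TRUE)
        fs <- fc_stack_forward(model, cs$flat, keep = TRUE)
        probs <- softmax_cols(fs$out)
        ep_loss <- ep_loss + batch_loss(probs, y1[idx]) * nb

        # backward: softmax cross-entropy
        dlog <- probs
        dlog[cbind(y1[idx], seq_len(nb))] <-
          dlog[cbind(y1[idx], seq_len(nb))] - 1
        dh <- dlog / nb
        for (i in rev(seq_along(model$fc))) {
          ca <- fs$caches[[i]]
          dz <- if (ca$head) dh else dh * (ca$z > 0)
          gW <- tcrossprod(dz, ca$x)
          gb <- rowSums(dz)
          dh <- crossprod(model$fc[[i]]$W, dz)
          upd("fc", i, "W", gW)
          upd("fc", i, "b", gb)
        }
        last <- cs$caches[[length(model$conv)]]
        dout <- array(dh, last$out_dim)
        for (i in rev(seq_along(model$conv))) {
          cl <- model$arch$conv[[i]]
          ca <- cs$caches[[i]]
          da <- if (is.null(cl$pool)) dout
                else .pool_bwd(dout, ca$out_dim, ca$a_dim, ca$idx,
                               cl$pool$size, cl$pool$stride,
                               cl$pool$type == "max")
          dz <- da * (ca$z > 0)
          bw <- .conv_bwd(ca$x, dim(ca$x), model$conv[[i]]$W, dz,
                          cl$k, cl$stride, cl$pad, i > 1L)
          upd("conv", i, "W", bw$dw)
          upd("conv", i, "b", bw$db)
          if (i > 1L) dout <- bw$dx
        }
      }
      model$loss_history <- c(model$loss_history, ep_loss / n)
    }
  })
  model$trained <- TRUE
  model$config <- config
  model
}

#' Classify a full image by majority vote over patch decisions
#'
#' Extracts patches of the model's input size from the image (regular grid
#' or random positions), normalizes and classifies each, and returns the
#' majority label with the winning vote share.  A tied vote (possible for
#' even patch counts) is resolved to abnormal, favouring sensitivity in a
#' screening setting.
#'
#' @param model A trained `scratch_cnn`.
#' @param img A `labeled_image` at least as large as the model input.
#' @param patch_strategy `list(type = "grid", stride = s)` or
#'   `list(type = "random", n = k, seed = s)`.  The default grid stride of
#'   32 on a 256-px image yields 25 patches.
#' @return List with `label` (0/1), `vote_fraction` (winning share) and
#'   `n_patches`.
#' @export
classify_image_vote <- function(model, img,
                                patch_strategy = list(type = "grid",
                                                      stride = 32L)) {
  stopifnot(inherits(model, "scratch_cnn"), inherits(img, "labeled_image"))
  P <- model$arch$input[1]
  ps <- switch(patch_strategy$type,
    grid = grid_patches(img, P, patch_strategy$stride),
    random = random_patches(img, P, patch_strategy$n,
                            patch_strategy$seed %||% 1L),
    stop("unknown patch strategy '", patch_strategy$type, "'"))
  votes <- predict(model, normalize_batch(ps$pixels), type = "class")
  c(majority_vote(votes), list(n_patches = length(votes)))
}

# Aggregate binary patch votes: majority label, ties resolved to abnormal
# (label 1); returns the winning share.  Invariant under any permutation
# or duplication of the vote vector.
majority_vote <- function(votes) {
  n <- length(votes)
  n_abn <- sum(votes == 1L)
  label <- as.integer(2L * n_abn >= n)   # tie -> abnormal
  winning <- if (label == 1L) n_abn else n - n_abn
  list(label = label, vote_fraction = winning / n)
}

#' Activation vector at a fully connected tap
#'
#' Runs the patch through the convolutional stack and the FC layers up to
#' the requested tap (`"PFCL"` = prior fully connected layer, `"LFCL"` =
#' last fully connected layer) and returns that layer's activations:
#' post-ReLU for hidden layers, raw logits for a classifier head.
#'
#' @param model A `scratch_cnn` (trained or untrained).
#' @param patch Array matching the model input.
#' @param tap `"PFCL"` or `"LFCL"`.
#' @return Numeric vector whose length is the tapped layer's width.
#' @export
extract_layer_vector <- function(model, patch, tap = c("PFCL", "LFCL")) {
  stopifnot(inherits(model, "scratch_cnn"))
  tap <- match.arg(tap)
  idx <- model$arch$taps[[tap]]
  if (is.na(idx) || is.null(idx))
    stop("architecture '", model$arch$name, "' has no ", tap, " tap")
  x <- check_patch_dim(model, patch)
  flat <- conv_stack_forward(model, x)$flat
  v <- as.numeric(fc_stack_forward(model, flat, upto = idx)$out)
  structure(v, provenance = list(extractor = model$arch$name, tap = tap))
}

#' Save model weights to a file
#'
#' Serializes the architecture description and all layer weights.
#'
#' @param model A `scratch_cnn`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_model_weights <- function(model, path) {
  stopifnot(inherits(model, "scratch_cnn"))
  saveRDS(list(arch_name = model$arch$name,
               conv = model$conv, fc = model$fc), path)
  invisible(path)
}

#' Install externally trained weights into a model
#'
#' Loads a weight file written by [save_model_weights()] (e.g. weights
#' converted from an ImageNet-trained network) and installs it into a
#' shape-compatible model, reporting every mismatched layer by name.
#'
#' @param model A `scratch_cnn` built from the matching architecture.
#' @param weight_file Path to the weight file.
#' @return The model with weights installed and `trained = TRUE`.
#' @export
load_external_weights <- function(model, weight_file) {
  stopifnot(inherits(model, "scratch_cnn"))
  if (!file.exists(weight_file)) stop("weight file not found: ", weight_file)
  w <- readRDS(weight_file)
  bad <- character(0)
  chk <- function(stored, own, label) {
    if (length(stored) != length(own)) return(label)
    for (i in seq_along(own))
      if (!identical(dim(stored[[i]]$W), dim(own[[i]]$W)) ||
          length(stored[[i]]$b) != length(own[[i]]$b))
        return(paste0(label, " layer ", i))
    NULL
  }
  bad <- c(chk(w$conv, model$conv, "conv"), chk(w$fc, model$fc, "fc"))
  if (length(bad))
    stop("weight shape mismatch at: ", paste(bad, collapse = ", "))
  model$conv <- w$conv
  model$fc <- w$fc
  model$trained <- TRUE
  model
}
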