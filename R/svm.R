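# Linear SVM on feature matrices, with fold-local feature standardization
# replayed identically at prediction time.

#' Train a linear SVM on a feature matrix
#'
#' Columns are z-scored with training-set statistics (concatenated feature
#' blocks live on wildly different scales); constant columns pass through
#' unscaled.  The same transform is replayed at prediction time.  The
#' classifier itself is the C-classification linear-kernel SVM from
#' \pkg{e1071}.
#'
#' @param X Numeric matrix, one row per image, columns aligned across rows.
#' @param labels Binary labels (0/1), one per row; both classes required.
#' @param C Regularization (cost) parameter.
#' @param standardize Whether to z-score columns with train statistics.
#' @return A `linear_svm` object.
#' @export
train_linear_svm <- function(X, labels, C = 1, standardize = TRUE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("feature matrix must be finite")
  labels <- as.integer(labels)
  if (nrow(X) != length(labels)) stop("one label per row required")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (standardize) {
    centre <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
  } else {
    centre <- numeric(ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, centre), 2, scl, "/")
  fit <- e1071::svm(Xs, factor(labels, levels = c(0L, 1L)),
                    kernel = "linear", cost = C, scale = FALSE)
  structure(list(fit = fit, centre = centre, scl = scl, p = ncol(X), C = C),
            class = "linear_svm")
}

#' Predict labels with a trained linear SVM
#'
#' @param classifier A `linear_svm`.
#' @param X Feature matrix with the same column count as at training.
#' @param decision Return raw decision values instead of labels.
#' @return Integer labels (0/1), or decision values when `decision = TRUE`.
#' @export
predict_svm <- function(classifier, X, decision = FALSE) {
  stopifnot(inherits(classifier, "linear_svm"))
  X <- as.matrix(X)
  if (ncol(X) != classifier$p)
    stop("feature dimension mismatch: got ", ncol(X),
         " columns, expected ", classifier$p)
  Xs <- sweep(sweep(X, 2, classifier$centre), 2, classifier$scl, "/")
  if (decision) {
    as.numeric(attr(predict(classifier$fit, Xs, decision.values = TRUE),
                    "decision.values"))
  } else {
    as.integer(as.character(predict(classifier$fit, Xs)))
  }
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("Linear SVM:", x$p, "features, C =", x$C, ",",
      x$fit$tot.nSV, "support vectors\n")
  invisible(x)
}
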