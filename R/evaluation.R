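# Patient-grouped cross-validation, accuracy, and exact McNemar
# comparison matrices.

new_fold_plan <- function(folds, patients) {
  structure(list(folds = folds, patients = patients), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("fold_plan:", length(x$folds), "folds over",
      length(x$patients), "patients\n")
  invisible(x)
}

validate_fold_plan <- function(plan) {
  test_all <- unlist(lapply(plan$folds, `[[`, "test"))
  if (anyDuplicated(test_all)) stop("test sets overlap across folds")
  if (!setequal(test_all, plan$patients))
    stop("union of test sets must equal the patient set")
  for (f in plan$folds)
    if (length(intersect(f$train, f$test)) > 0)
      stop("train and test patients overlap within a fold")
  invisible(plan)
}

#' Leave-one-patient-out fold plan
#'
#' One fold per patient: all images of that patient form the test set and
#' every other patient's images the training set, so no image (in any
#' augmented or cropped form, which always follows its parent's patient)
#' of a test patient can leak into training.
#'
#' @param cohort A `polyp_cohort` with at least 2 patients.
#' @return A `fold_plan`.
#' @export
lopo_folds <- function(cohort) {
  stopifnot(inherits(cohort, "polyp_cohort"))
  patients <- unique(cohort$metadata$patient_id)
  if (length(patients) < 2L) stop("need at least 2 patients")
  folds <- lapply(patients, function(p)
    list(train = setdiff(patients, p), test = p))
  validate_fold_plan(new_fold_plan(folds, patients))
}

#' Patient-grouped k-fold plan with prescribed test-set sizes
#'
#' Randomly partitions the patients into test sets of the given sizes
#' (which must sum to the patient count), e.g. `c(rep(6, 9), 8)` for the
#' 10-fold design testing 6 patients in nine folds and 8 in the last, so
#' that every patient is tested exactly once.
#'
#' @param cohort A `polyp_cohort`.
#' @param sizes Integer vector of per-fold test-set sizes.
#' @param seed Integer seed for the patient permutation.
#' @return A `fold_plan`.
#' @export
grouped_kfold <- function(cohort, sizes, seed = 1L) {
  stopifnot(inherits(cohort, "polyp_cohort"))
  patients <- unique(cohort$metadata$patient_id)
  if (sum(sizes) != length(patients))
    stop("test-set sizes must sum to the patient count (",
         length(patients), ")")
  if (any(sizes >= length(patients)))
    stop("a fold testing every patient would leave an empty training set")
  if (any(sizes < 1)) stop("test-set sizes must be positive")
  perm <- with_seed(seed, sample(patients))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  folds <- lapply(seq_along(sizes), function(i) {
    test <- perm[starts[i]:ends[i]]
    list(train = setdiff(patients, test), test = test)
  })
  validate_fold_plan(new_fold_plan(folds, patients))
}

#' Image-level classification accuracy
#'
#' @param records Data frame of prediction records with columns `true` and
#'   `predicted` (one row per image, post-voting).
#' @return Fraction of correctly classified images.
#' @export
accuracy <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no prediction records")
  mean(records$predicted == records$true)
}

#' Exact McNemar test between two classifiers
#'
#' Compares paired predictions over the same images via the discordant
#' counts n01 (first correct, second wrong) and n10 (the reverse), using
#' the exact two-sided binomial test
#' `p = min(1, 2 * P(Bin(n01 + n10, 1/2) <= min(n01, n10)))`, with `p = 1`
#' when there is no discordance.  Concordant pairs carry no information
#' and are ignored.
#'
#' @param a,b Prediction-record data frames with columns `image_id`,
#'   `true`, `predicted` over the same image set with the same truths.
#' @return The exact two-sided p-value.
#' @export
mcnemar_exact <- function(a, b) {
  if (!setequal(a$image_id, b$image_id))
    stop("the two record sets cover different images")
  b <- b[match(a$image_id, b$image_id), ]
  if (!all(a$true == b$true))
    stop("true labels disagree between the two record sets")
  ca <- a$predicted == a$true
  cb <- b$predicted == b$true
  n01 <- sum(ca & !cb)
  n10 <- sum(!ca & cb)
  n <- n01 + n10
  if (n == 0L) return(1)
  min(1, 2 * pbinom(min(n01, n10), n, 0.5))
}

#' Pairwise McNemar significance matrix
#'
#' Computes [mcnemar_exact()] for every method pair over a common image
#' set and flags pairs with `p < alpha`.  Per-pair significance is
#' reported without multiple-testing correction; the diagonal is p = 1.
#'
#' @param all_records Named list of prediction-record data frames (>= 2
#'   methods).
#' @param alpha Significance level (0.01 and 0.05 are the conventional
#'   renderings).
#' @return A `comparison_matrix`: list with `p` (symmetric p-value
#'   matrix), `significant` (logical matrix), `alpha`.
#' @export
significance_matrix <- function(all_records, alpha = 0.01) {
  if (length(all_records) < 2L) stop("need at least 2 methods")
  methods <- names(all_records)
  k <- length(methods)
  p <- matrix(1, k, k, dimnames = list(methods, methods))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pv <- mcnemar_exact(all_records[[i]], all_records[[j]])
      p[i, j] <- pv
      p[j, i] <- pv
    }
  }
  structure(list(p = p, significant = p < alpha, alpha = alpha),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, digits = 4, ...) {
  cat("McNemar comparison matrix (alpha =", x$alpha, ")\n")
  print(round(x$p, digits))
  cat("significant pairs marked TRUE:\n")
  print(x$significant)
  invisible(x)
}
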