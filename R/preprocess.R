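# Augmentation, patch extraction, balanced sampling and normalization.

flip_h <- function(px) px[, dim(px)[2]:1, , drop = FALSE]
flip_v <- function(px) px[dim(px)[1]:1, , , drop = FALSE]
rot_cw <- function(px) {
  out <- aperm(px, c(2, 1, 3))
  out[, dim(out)[2]:1, , drop = FALSE]
}
rot_ccw <- function(px) {
  out <- aperm(px, c(2, 1, 3))
  out[dim(out)[1]:1, , , drop = FALSE]
}

#' Seven-transform augmentation of one image
#'
#' Produces, in this fixed order: horizontal flip, vertical flip, 90-degree
#' right rotation, 90-degree left rotation, horizontal flip of the right
#' rotation, horizontal flip of the left rotation, and vertical flip of the
#' horizontal flip (a 180-degree rotation) -- seven new samples per
#' original.  Each output keeps the parent's patient id and label and gets
#' a derived image id.
#'
#' @param img A `labeled_image` with square pixels (rotations would change
#'   the shape of a non-square image, so those are rejected).
#' @return List of 7 `labeled_image` objects.
#' @export
augment_image <- function(img) {
  stopifnot(inherits(img, "labeled_image"))
  d <- dim(img$pixels)
  if (d[1] != d[2]) stop("augment_image requires a square image")
  px <- img$pixels
  variants <- list(
    hf      = flip_h(px),
    vf      = flip_v(px),
    r90r    = rot_cw(px),
    r90l    = rot_ccw(px),
    r90r_hf = flip_h(rot_cw(px)),
    r90l_hf = flip_h(rot_ccw(px)),
    hf_vf   = flip_v(flip_h(px))
  )
  lapply(names(variants), function(tag)
    new_labeled_image(variants[[tag]], paste0(img$image_id, "_", tag),
                      img$patient_id, img$label, img$modality))
}

#' Augment a whole cohort
#'
#' Applies [augment_image()] to every image and returns a cohort containing
#' the originals plus the seven derived samples each, i.e. eight times the
#' input size.  Derived images keep their parent's patient id, so
#' patient-grouped cross-validation remains leakage-free after
#' augmentation.
#'
#' @param cohort A `polyp_cohort` of square images.
#' @return A `polyp_cohort` with `8 * nrow(metadata)` images.
#' @export
augment_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "polyp_cohort"))
  out <- vector("list", 8L * length(cohort$images))
  k <- 0L
  for (img in cohort$images) {
    out[[k + 1L]] <- img
    aug <- augment_image(img)
    for (j in 1:7) out[[k + 1L + j]] <- aug[[j]]
    k <- k + 8L
  }
  validate_cohort(new_cohort(out))
}

new_patch_set <- function(pixels, meta) {
  structure(list(pixels = pixels, meta = meta), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("patch_set:", nrow(x$meta), "patches",
      if (!is.null(x$pixels) && nrow(x$meta) > 0)
        paste0("of size ", dim(x$pixels)[1], "x", dim(x$pixels)[2])
      else "(offsets only)", "\n")
  invisible(x)
}

patch_meta_row <- function(img, row0, col0) {
  data.frame(image_id = img$image_id, patient_id = img$patient_id,
             label = img$label, row = row0, col = col0,
             stringsAsFactors = FALSE)
}

extract_patch_array <- function(px, offsets, P) {
  n <- nrow(offsets)
  out <- array(0, c(P, P, 3, max(n, 1L)))
  for (i in seq_len(n))
    out[, , , i] <- px[offsets$row[i] + seq_len(P),
                       offsets$col[i] + seq_len(P), , drop = FALSE]
  if (n == 0L) out <- array(0, c(P, P, 3, 0L))
  out
}

#' Regular grid of overlapping patches
#'
#' Extracts square patches whose 0-based top-left offsets are all multiples
#' of the stride `s` in the closed interval `[0, side - P]`, on both axes,
#' in row-major order.  The patch count is
#' `(floor((side - P) / s) + 1)^2`; for a 256-pixel image and 128-pixel
#' patches this yields 676, 49, 25 and 9 patches at strides 5, 20, 32
#' and 48.
#'
#' @param img A `labeled_image`.
#' @param patch_size Patch side length P in px (<= image side).
#' @param stride Offset step s in px (>= 1).
#' @param materialize Extract pixel arrays (`TRUE`) or return offsets only.
#' @return A `patch_set`: `pixels` (P x P x 3 x n array, `NULL` when not
#'   materialized) and `meta` (image_id, patient_id, label, row, col with
#'   0-based offsets).
#' @export
grid_patches <- function(img, patch_size, stride, materialize = TRUE) {
  stopifnot(inherits(img, "labeled_image"))
  side <- dim(img$pixels)[1]
  if (patch_size > side) stop("patch_size exceeds image side")
  if (!is_count(stride) || stride < 1) stop("stride must be a positive integer")
  pos <- as.integer(seq(0L, side - patch_size, by = stride))
  offsets <- expand.grid(col = pos, row = pos)[, c("row", "col")]
  # row-major: row varies slowest
  offsets <- offsets[order(offsets$row, offsets$col), , drop = FALSE]
  meta <- do.call(rbind, lapply(seq_len(nrow(offsets)), function(i)
    patch_meta_row(img, offsets$row[i], offsets$col[i])))
  px <- if (materialize)
    extract_patch_array(img$pixels, offsets, patch_size) else NULL
  new_patch_set(px, meta)
}

#' Random patch extraction
#'
#' Draws `n` square patches whose top-left offsets are i.i.d. uniform (with
#' replacement) over all valid stride-1 positions.  Deterministic given
#' `seed`.
#'
#' @inheritParams grid_patches
#' @param n Number of patches.
#' @param seed Integer seed.
#' @return A `patch_set`.
#' @export
random_patches <- function(img, patch_size, n, seed = 1L,
                           materialize = TRUE) {
  stopifnot(inherits(img, "labeled_image"))
  side <- dim(img$pixels)[1]
  if (patch_size > side) stop("patch_size exceeds image side")
  if (!is_count(n)) stop("n must be a nonnegative integer")
  offsets <- with_seed(seed, data.frame(
    row = sample.int(side - patch_size + 1L, n, replace = TRUE) - 1L,
    col = sample.int(side - patch_size + 1L, n, replace = TRUE) - 1L
  ))
  meta <- if (n > 0)
    do.call(rbind, lapply(seq_len(n), function(i)
      patch_meta_row(img, offsets$row[i], offsets$col[i])))
  else patch_meta_row(img, 0L, 0L)[0, ]
  px <- if (materialize)
    extract_patch_array(img$pixels, offsets, patch_size) else NULL
  new_patch_set(px, meta)
}

#' Class-balanced random patch sampling over a cohort
#'
#' Draws, from every image, a number of random patches determined by the
#' image's class (`per_class_counts`, e.g. `c(healthy = 75, abnormal =
#' 25)`).  Choosing counts inversely proportional to the class image counts
#' balances the per-class patch totals, the usual remedy for a skewed
#' healthy/abnormal ratio.  A class requested with a positive count but
#' absent from the cohort triggers a warning and is skipped.
#'
#' @param cohort A `polyp_cohort` (typically after [augment_cohort()]).
#' @param patch_size Patch side length in px.
#' @param per_class_counts Named numeric vector or list with elements
#'   `healthy` and `abnormal`: patches to draw per image of that class.
#' @param seed Integer seed; per-image substreams are derived from it.
#' @return A `patch_set` combining all drawn patches.
#' @export
sample_balanced <- function(cohort, patch_size,
                            per_class_counts = c(healthy = 75, abnormal = 25),
                            seed = 1L) {
  stopifnot(inherits(cohort, "polyp_cohort"))
  counts <- as.list(per_class_counts)
  if (any(unlist(counts) < 0)) stop("per-class counts must be nonnegative")
  labs <- cohort$metadata$label
  for (cls in c("healthy", "abnormal")) {
    want <- counts[[cls]] %||% 0
    present <- any(labs == (cls == "abnormal"))
    if (want > 0 && !present)
      warning("no ", cls, " images present; requested patches skipped")
  }
  sets <- list()
  for (img in cohort$images) {
    cls <- if (img$label == 1L) "abnormal" else "healthy"
    n <- counts[[cls]] %||% 0
    if (n == 0) next
    sets[[length(sets) + 1L]] <-
      random_patches(img, patch_size, n,
                     seed = derive_seed(seed, paste0("patch/", img$image_id)))
  }
  if (length(sets) == 0L)
    return(new_patch_set(array(0, c(patch_size, patch_size, 3, 0)),
                         patch_meta_row(cohort$images[[1]], 0L, 0L)[0, ]))
  new_patch_set(
    array(unlist(lapply(sets, `[[`, "pixels")),
          c(patch_size, patch_size, 3, sum(vapply(sets, function(s)
            nrow(s$meta), 0L)))),
    do.call(rbind, lapply(sets, `[[`, "meta"))
  )
}

#' Per-patch normalization
#'
#' Subtracts the mean and divides by the population standard deviation of
#' all elements of the patch (all pixels and channels jointly), the local
#' brightness/contrast normalization applied before CNN training.  A
#' constant patch maps to all zeros rather than dividing by zero.
#'
#' @param p A P x P x 3 array (or any numeric array).
#' @return Array of the same shape with element mean 0 and population
#'   standard deviation 1 (or all zeros for a degenerate input).
#' @export
normalize_patch <- function(p) {
  m <- mean(p)
  s <- pop_sd(p)
  if (s < 1e-12) return(p * 0)
  (p - m) / s
}

# Normalize every patch of a 4D batch (P, P, 3, N) in place.
normalize_batch <- function(x) {
  n <- dim(x)[4]
  for (i in seq_len(n)) x[, , , i] <- normalize_patch(x[, , , i])
  x
}
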