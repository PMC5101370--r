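#' Specify a synthetic endoscopy-like texture cohort
#'
#' Builds the parameter object consumed by [generate_cohort()].  The
#' generator emulates the statistical structure of a two-class colonic-polyp
#' still-image database: a fixed number of patients, several images per
#' patient, and a binary histology-style label per image
#' (0 = non-neoplastic/"healthy", 1 = neoplastic/"abnormal").  Images are
#' mucosa-toned backgrounds carrying dark elliptical "pit" blobs whose
#' density, size, elongation and contrast differ between classes, with
#' endoscopy nuisances (illumination gradient, blur, specular highlights)
#' applied after texture synthesis.
#'
#' A patient may contribute images of both classes: each image's label is
#' drawn per-patient with probability `class_assignment` of being abnormal,
#' mirroring databases whose per-class patient counts sum to more than the
#' patient total.
#'
#' The `difficulty` scalar linearly shrinks the two classes' texture
#' parameters towards their common midpoint: at `difficulty = 0` the class
#' parameter supports are as configured (disjoint under the defaults), at
#' `difficulty = 1` the classes are identical and no classifier can beat
#' chance.
#'
#' @param n_patients Number of patients.
#' @param images_per_patient Integer vector `c(min, max)`; per-patient image
#'   counts are drawn uniformly from this range unless `n_images` is given.
#' @param n_images Optional total image count.  When supplied, images are
#'   allocated as evenly as possible across patients (every patient gets at
#'   least one) so that the cohort has exactly this many images.
#' @param image_size Side length in pixels of the square images.
#' @param class_assignment Per-patient probability that an image is abnormal.
#' @param texture_params List with elements `healthy` and `abnormal`, each a
#'   list with `density` (blobs per 10^4 px), `radius_mean`, `radius_sd`
#'   (px), `elongation` (axis ratio, >= 1) and `contrast` (fraction of the
#'   dynamic range removed at a pit centre).
#' @param patient_effect_sd Standard deviation of the per-patient
#'   multiplicative log-normal jitter applied to the texture parameters.
#' @param nuisance List with `illumination` (gradient amplitude as a
#'   fraction), `blur_sigma` (range `c(min, max)` in px) and `specular`
#'   (highlight count range `c(min, max)`).  Set amplitudes to zero for
#'   nuisance-free rendering; labels and metadata are unaffected.
#' @param difficulty Scalar in `[0, 1]` scaling inter-class overlap.
#' @param modality Free-text tag recorded per image (e.g. an imaging-mode
#'   name).
#' @param seed Master integer seed.  Per-image substreams are derived by a
#'   stable hash of `(patient_id, image index)`.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_patients = 62,
                        images_per_patient = c(1, 3),
                        n_images = 100,
                        image_size = 256,
                        class_assignment = 0.75,
                        texture_params = default_texture_params(),
                        patient_effect_sd = 0.05,
                        nuisance = list(illumination = 0.15,
                                        blur_sigma = c(0, 1),
                                        specular = c(0, 4)),
                        difficulty = 0.3,
                        modality = "synthetic",
                        seed = 1L) {
  spec <- structure(list(
    n_patients = n_patients, images_per_patient = images_per_patient,
    n_images = n_images, image_size = image_size,
    class_assignment = class_assignment, texture_params = texture_params,
    patient_effect_sd = patient_effect_sd, nuisance = nuisance,
    difficulty = difficulty, modality = modality, seed = seed
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Default class texture parameters
#'
#' Non-neoplastic mucosa is rendered with round, moderately dense, lower
#' contrast pits; neoplastic mucosa with elongated, larger, higher-contrast
#' pits, reflecting the elongation/irregularity that separates pit-pattern
#' classes.
#'
#' @return List with `healthy` and `abnormal` parameter lists.
#' @export
default_texture_params <- function() {
  list(
    healthy  = list(density = 12, radius_mean = 3.0, radius_sd = 0.5,
                    elongation = 1.2, contrast = 0.35),
    abnormal = list(density = 8,  radius_mean = 3.6, radius_sd = 0.6,
                    elongation = 3.0, contrast = 0.55)
  )
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is_count(spec$n_patients))
    stop("n_patients must be a nonnegative integer")
  if (!is.null(spec$n_images)) {
    if (!is_count(spec$n_images)) stop("n_images must be a nonnegative integer")
    if (spec$n_patients > 0 && spec$n_images < spec$n_patients)
      stop("n_images must be >= n_patients (every patient contributes an image)")
  } else {
    ipp <- spec$images_per_patient
    if (length(ipp) != 2L || any(ipp < 0) || ipp[1] > ipp[2])
      stop("images_per_patient must be c(min, max) with 0 <= min <= max")
  }
  if (!is.numeric(spec$difficulty) || spec$difficulty < 0 || spec$difficulty > 1)
    stop("difficulty must lie in [0, 1]")
  if (spec$class_assignment < 0 || spec$class_assignment > 1)
    stop("class_assignment must lie in [0, 1]")
  if (!is_count(spec$image_size) || spec$image_size < 16)
    stop("image_size must be an integer >= 16")
  for (cls in c("healthy", "abnormal")) {
    tp <- spec$texture_params[[cls]]
    if (is.null(tp)) stop("texture_params must have 'healthy' and 'abnormal'")
    need <- c("density", "radius_mean", "radius_sd", "elongation", "contrast")
    if (!all(need %in% names(tp)))
      stop("texture_params$", cls, " must contain: ", paste(need, collapse = ", "))
    if (tp$elongation < 1) stop("elongation must be >= 1")
    if (any(unlist(tp[need]) < 0)) stop("texture parameters must be nonnegative")
  }
  invisible(spec)
}

# Interpolate each class's texture parameters towards the class midpoint as
# difficulty rises: d = 0 keeps them as configured, d = 1 makes them equal.
effective_class_params <- function(spec) {
  h <- spec$texture_params$healthy
  a <- spec$texture_params$abnormal
  d <- spec$difficulty
  fields <- c("density", "radius_mean", "radius_sd", "elongation", "contrast")
  out <- list(healthy = h, abnormal = a)
  for (f in fields) {
    mid <- (h[[f]] + a[[f]]) / 2
    out$healthy[[f]]  <- mid + (1 - d) * (h[[f]] - mid)
    out$abnormal[[f]] <- mid + (1 - d) * (a[[f]] - mid)
  }
  out$healthy$elongation  <- max(1, out$healthy$elongation)
  out$abnormal$elongation <- max(1, out$abnormal$elongation)
  out
}

new_labeled_image <- function(pixels, image_id, patient_id, label, modality) {
  structure(list(pixels = pixels, image_id = image_id,
                 patient_id = patient_id, label = as.integer(label),
                 modality = modality),
            class = "labeled_image")
}

validate_labeled_image <- function(img) {
  d <- dim(img$pixels)
  if (length(d) != 3L || d[3] != 3L || d[1] != d[2])
    stop("image '", img$image_id, "': pixels must be a square H x W x 3 array")
  if (!all(is.finite(img$pixels)) || any(img$pixels < 0) || any(img$pixels > 1))
    stop("image '", img$image_id, "': pixels must be finite and within [0, 1]")
  if (!img$label %in% c(0L, 1L))
    stop("image '", img$image_id, "': label must be 0 or 1")
  invisible(img)
}

new_cohort <- function(images, modality = "synthetic") {
  meta <- if (length(images) == 0L) {
    data.frame(image_id = character(), patient_id = character(),
               label = integer(), modality = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      image_id   = vapply(images, `[[`, "", "image_id"),
      patient_id = vapply(images, `[[`, "", "patient_id"),
      label      = vapply(images, `[[`, 0L, "label"),
      modality   = vapply(images, `[[`, "", "modality"),
      stringsAsFactors = FALSE
    )
  }
  structure(list(images = images, metadata = meta), class = "polyp_cohort")
}

validate_cohort <- function(cohort) {
  meta <- cohort$metadata
  if (length(cohort$images) != nrow(meta))
    stop("metadata rows and image count differ")
  if (anyDuplicated(meta$image_id))
    stop("duplicate image_id: ",
         paste(unique(meta$image_id[duplicated(meta$image_id)]), collapse = ", "))
  for (img in cohort$images) validate_labeled_image(img)
  invisible(cohort)
}

#' Generate a synthetic patient-structured polyp-image cohort
#'
#' Renders every image of the cohort described by a [cohort_spec()].
#' Generation is fully deterministic given the spec's seed.  Per-patient
#' texture jitter and per-image labels are drawn from a patient-level
#' substream; each image's texture and nuisances come from an image-level
#' substream keyed by `(patient_id, image index)`, so enlarging a cohort
#' never reshuffles previously generated images.  Nuisances are applied
#' after texture synthesis and never influence labels or metadata.
#'
#' @param spec A [cohort_spec()].
#' @return A `polyp_cohort`: list with `images` (list of `labeled_image`,
#'   each holding an `image_size` x `image_size` x 3 array in `[0, 1]`) and
#'   `metadata` (data frame with `image_id`, `patient_id`, `label`,
#'   `modality`).
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 3, n_images = 5,
#'                                   image_size = 64, seed = 7))
#' co$metadata
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  if (spec$n_patients == 0L) return(new_cohort(list()))

  params <- effective_class_params(spec)
  patient_ids <- sprintf("P%03d", seq_len(spec$n_patients))

  # per-patient image counts
  counts <- if (!is.null(spec$n_images)) {
    base <- spec$n_images %/% spec$n_patients
    extra <- spec$n_images %% spec$n_patients
    base + as.integer(seq_len(spec$n_patients) <= extra)
  } else {
    vapply(patient_ids, function(pid)
      with_seed(derive_seed(spec$seed, paste0("count/", pid)),
                sample(seq(spec$images_per_patient[1],
                           spec$images_per_patient[2]), 1L)),
      0L)
  }

  images <- vector("list", sum(counts))
  k <- 0L
  for (i in seq_along(patient_ids)) {
    pid <- patient_ids[i]
    # patient-level substream: texture jitter + labels, independent of
    # nuisance settings
    pstate <- with_seed(derive_seed(spec$seed, paste0("patient/", pid)), {
      jitter <- exp(rnorm(4, 0, spec$patient_effect_sd))
      labels <- rbinom(counts[i], 1L, spec$class_assignment)
      list(jitter = jitter, labels = labels)
    })
    for (j in seq_len(counts[i])) {
      lab <- pstate$labels[j]
      tp <- if (lab == 1L) params$abnormal else params$healthy
      tp$density     <- tp$density * pstate$jitter[1]
      tp$radius_mean <- tp$radius_mean * pstate$jitter[2]
      tp$elongation  <- max(1, tp$elongation * pstate$jitter[3])
      tp$contrast    <- min(0.95, tp$contrast * pstate$jitter[4])
      image_id <- sprintf("%s_I%03d", pid, j)
      pixels <- with_seed(derive_seed(spec$seed, paste0("image/", pid, "/", j)), {
        px <- render_texture(spec$image_size, tp)
        apply_nuisances(px, spec$nuisance)
      })
      k <- k + 1L
      images[[k]] <- new_labeled_image(pixels, image_id, pid, lab, spec$modality)
    }
  }
  validate_cohort(new_cohort(images))
}

# Render one mucosa-toned image with dark elliptical pit blobs.
# Elliptical axes are radius*sqrt(e) and radius/sqrt(e), keeping blob area
# independent of elongation so that elongation is a pure shape cue.
render_texture <- function(size, tp) {
  base_tone <- c(0.80, 0.55, 0.50)
  # smooth background modulation: bicubically upsampled low-res noise
  coarse <- matrix(rnorm(16, 0, 1), 4, 4)
  bg_mod <- resize_matrix_bicubic(coarse, size) * 0.04

  dark <- matrix(0, size, size)  # accumulated pit darkening in [0, 1)
  n_blobs <- rpois(1, tp$density * size^2 / 1e4)
  if (n_blobs > 0) {
    cx <- runif(n_blobs, 1, size)
    cy <- runif(n_blobs, 1, size)
    rad <- pmax(0.6, rnorm(n_blobs, tp$radius_mean, tp$radius_sd))
    elo <- pmax(1, rnorm(n_blobs, tp$elongation, 0.08 * tp$elongation))
    th <- runif(n_blobs, 0, pi)
    dep <- tp$contrast * runif(n_blobs, 0.85, 1.15)
    for (b in seq_len(n_blobs)) {
      a_ax <- rad[b] * sqrt(elo[b])      # major semi-axis
      b_ax <- rad[b] / sqrt(elo[b])      # minor semi-axis
      ext <- ceiling(2.5 * a_ax)
      rows <- max(1, floor(cy[b] - ext)):min(size, ceiling(cy[b] + ext))
      cols <- max(1, floor(cx[b] - ext)):min(size, ceiling(cx[b] + ext))
      dy <- rows - cy[b]
      dx <- cols - cx[b]
      # rotated anisotropic Gaussian profile
      u <- outer(dy, dx, function(y, x)  x * cos(th[b]) + y * sin(th[b]))
      v <- outer(dy, dx, function(y, x) -x * sin(th[b]) + y * cos(th[b]))
      g <- dep[b] * exp(-0.5 * ((u / a_ax)^2 + (v / b_ax)^2) * 2)
      dark[rows, cols] <- pmax(dark[rows, cols], g)
    }
  }
  px <- array(0, c(size, size, 3))
  for (ch in 1:3)
    px[, , ch] <- clamp01((base_tone[ch] + bg_mod) * (1 - dark))
  px
}

apply_nuisances <- function(px, nuisance) {
  size <- dim(px)[1]
  illum <- nuisance$illumination %||% 0
  if (illum > 0) {
    phi <- runif(1, 0, 2 * pi)
    g <- outer(seq_len(size), seq_len(size), function(y, x)
      ((x - size / 2) * cos(phi) + (y - size / 2) * sin(phi)) / size)
    for (ch in 1:3) px[, , ch] <- px[, , ch] * (1 + 2 * illum * g)
  }
  bs <- nuisance$blur_sigma %||% c(0, 0)
  sigma <- runif(1, bs[1], bs[2])
  if (sigma > 0.05) px <- gaussian_blur(px, sigma)
  sp <- nuisance$specular %||% c(0, 0)
  n_spec <- if (sp[2] > 0) sample(sp[1]:sp[2], 1L) else 0L
  if (n_spec > 0) {
    for (s in seq_len(n_spec)) {
      cx <- runif(1, 1, size); cy <- runif(1, 1, size)
      r <- runif(1, 2, 5)
      ext <- ceiling(3 * r)
      rows <- max(1, floor(cy - ext)):min(size, ceiling(cy + ext))
      cols <- max(1, floor(cx - ext)):min(size, ceiling(cx + ext))
      g <- outer(rows - cy, cols - cx, function(y, x)
        exp(-0.5 * (x^2 + y^2) / r^2)) * 0.9
      for (ch in 1:3)
        px[rows, cols, ch] <- px[rows, cols, ch] +
          (1 - px[rows, cols, ch]) * g
    }
  }
  clamp01(px)
}

# Separable Gaussian blur with edge-renormalized (truncated) kernel, so
# borders are neither darkened nor wrapped.
gaussian_blur <- function(px, sigma) {
  size <- dim(px)[1]
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-0.5 * ((-half):half)^2 / sigma^2)
  B <- matrix(0, size, size)
  for (i in seq_len(size)) {
    lo <- max(1, i - half); hi <- min(size, i + half)
    w <- kern[(lo - i + half + 1):(hi - i + half + 1)]
    B[i, lo:hi] <- w / sum(w)
  }
  for (ch in 1:3) px[, , ch] <- B %*% px[, , ch] %*% t(B)
  px
}

#' @export
print.polyp_cohort <- function(x, ...) {
  n <- nrow(x$metadata)
  cat("polyp_cohort:", n, "images,",
      length(unique(x$metadata$patient_id)), "patients\n")
  if (n > 0) {
    tab <- table(factor(x$metadata$label, levels = c(0, 1),
                        labels = c("healthy", "abnormal")))
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  image size:", dim(x$images[[1]]$pixels)[1], "px, modality:",
        x$metadata$modality[1], "\n")
  }
  invisible(x)
}

#' @export
summary.polyp_cohort <- function(object, ...) {
  meta <- object$metadata
  out <- list(
    n_images = nrow(meta),
    n_patients = length(unique(meta$patient_id)),
    per_class_images = table(meta$label),
    per_class_patients = tapply(meta$patient_id, meta$label,
                                function(p) length(unique(p)))
  )
  class(out) <- "summary.polyp_cohort"
  out
}

#' @export
print.summary.polyp_cohort <- function(x, ...) {
  cat("Images:", x$n_images, " Patients:", x$n_patients, "\n")
  cat("Images per class:\n"); print(x$per_class_images)
  cat("Patients per class:\n"); print(x$per_class_patients)
  invisible(x)
}

#' Write a cohort to disk as PNGs plus a CSV manifest
#'
#' One 8-bit RGB PNG per image (named `<image_id>.png`) and a
#' `metadata.csv` manifest with columns `image_id`, `patient_id`, `label`,
#' `modality`.  The round trip through [read_cohort()] preserves metadata
#' exactly and pixels to within 8-bit quantization (1/255).
#'
#' @param cohort A `polyp_cohort`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, directory) {
  validate_cohort(cohort)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (img in cohort$images)
    png::writePNG(img$pixels, file.path(directory, paste0(img$image_id, ".png")))
  write.csv(cohort$metadata, file.path(directory, "metadata.csv"),
            row.names = FALSE)
  invisible(cohort$metadata)
}

#' Read a cohort written by [write_cohort()]
#'
#' Reconstructs the `polyp_cohort` from a directory containing
#' `metadata.csv` and one PNG per metadata row, validating all container
#' invariants (unique image ids, one image per row, pixels in `[0, 1]`).
#'
#' @param directory Directory holding the manifest and PNGs.
#' @return A `polyp_cohort`.
#' @export
read_cohort <- function(directory) {
  manifest <- file.path(directory, "metadata.csv")
  if (!file.exists(manifest)) stop("no metadata.csv manifest in ", directory)
  meta <- read.csv(manifest, stringsAsFactors = FALSE,
                   colClasses = c(image_id = "character",
                                  patient_id = "character"))
  if (anyDuplicated(meta$image_id))
    stop("duplicate image_id in manifest: ",
         paste(unique(meta$image_id[duplicated(meta$image_id)]), collapse = ", "))
  images <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    f <- file.path(directory, paste0(meta$image_id[i], ".png"))
    if (!file.exists(f))
      stop("missing image file for metadata row ", i,
           " (image_id '", meta$image_id[i], "')")
    px <- png::readPNG(f)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
    images[[i]] <- new_labeled_image(px[, , 1:3, drop = FALSE],
                                     meta$image_id[i], meta$patient_id[i],
                                     meta$label[i], meta$modality[i])
  }
  validate_cohort(new_cohort(images))
}
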