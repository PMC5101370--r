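# Config-driven experiment orchestration: generate (or load) a cohort,
# run each configured method under a patient-grouped fold plan, and
# aggregate accuracies plus McNemar comparison matrices into a report.

known_method_types <- c("cnn_scratch", "cnn_svm", "feature_svm")
known_extractors <- c("mb_lbp", "gwt_weibull", "offshelf")

validate_pipeline_config <- function(config) {
  if (is.null(config$methods) || length(config$methods) == 0L)
    stop("config must name at least one method")
  nms <- vapply(config$methods, function(m) m$name %||% "", "")
  if (any(nms == "") || anyDuplicated(nms))
    stop("every method needs a unique 'name'")
  for (m in config$methods) {
    type <- m$type %||% ""
    if (!type %in% known_method_types)
      stop("unknown method type '", type, "' for method '", m$name,
           "' (known: ", paste(known_method_types, collapse = ", "), ")")
    if (type == "feature_svm") {
      feats <- unlist(m$features)
      if (is.null(feats)) stop("method '", m$name, "' lists no features")
      base <- sub(":.*$", "", feats)
      bad <- setdiff(base, known_extractors)
      if (length(bad))
        stop("unknown feature extractor(s) for method '", m$name, "': ",
             paste(bad, collapse = ", "))
    }
  }
  fs <- config$folds$strategy %||% "lopo"
  if (!fs %in% c("lopo", "grouped"))
    stop("unknown fold strategy '", fs, "'")
  invisible(config)
}

# Build one feature extractor closure from its config name, e.g. "mb_lbp"
# or "offshelf:VGG-VD16:PFCL".
make_extractor <- function(name, params = list(), seed = 1L) {
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  base <- parts[1]
  switch(base,
    mb_lbp = {
      scales <- params$block_scales %||% c(1L, 3L, 5L)
      function(img) mb_lbp_features(img, block_scales = scales)
    },
    gwt_weibull = {
      ns <- params$n_scales %||% 4L
      no <- params$n_orientations %||% 6L
      function(img) gwt_weibull_features(img, n_scales = ns,
                                         n_orientations = no)
    },
    offshelf = {
      arch <- if (length(parts) >= 2) parts[2] else "VGG-VD16"
      tap <- if (length(parts) >= 3) parts[3] else "PFCL"
      model <- build_model(offshelf_arch(arch), seed = seed)
      function(img)
        extract_offshelf_features(model,
                                  resize_bicubic(img, model$arch$input[1]),
                                  tap = tap)
    },
    stop("unknown feature extractor '", name, "'"))
}

# Feature matrix for every image of the cohort (rows aligned to metadata).
cohort_feature_matrix <- function(cohort, extractors) {
  rows <- lapply(cohort$images, function(img)
    fuse_features(lapply(extractors, function(ex) ex(img))))
  X <- do.call(rbind, rows)
  rownames(X) <- cohort$metadata$image_id
  X
}

records_df <- function(ids, true, predicted, method, fold) {
  data.frame(image_id = ids, true = as.integer(true),
             predicted = as.integer(predicted), method = method,
             fold = fold, stringsAsFactors = FALSE)
}

fold_index <- function(cohort, plan) {
  lapply(plan$folds, function(f)
    list(train = which(cohort$metadata$patient_id %in% f$train),
         test = which(cohort$metadata$patient_id %in% f$test)))
}

sub_cohort <- function(cohort, idx)
  new_cohort(cohort$images[idx])

run_cnn_scratch_method <- function(m, cohort, plan, seed) {
  arch <- m$arch %||% "CNN-05"
  tc_args <- m$train %||% list()
  vote <- m$vote %||% list(type = "grid", stride = 32L)
  counts <- m$per_class_counts %||% list(healthy = 6, abnormal = 6)
  P <- scratch_arch(arch)$input[1]
  idx <- fold_index(cohort, plan)
  recs <- list()
  for (k in seq_along(idx)) {
    fold_seed <- derive_seed(seed, paste0("fold/", m$name, "/", k))
    train_co <- sub_cohort(cohort, idx[[k]]$train)
    if (isTRUE(m$augment)) train_co <- augment_cohort(train_co)
    patches <- sample_balanced(train_co, P, counts, seed = fold_seed)
    cfg <- do.call(train_config, c(tc_args, list(seed = fold_seed)))
    model <- build_model(scratch_arch(arch), seed = fold_seed)
    model <- train_cnn(model, patches, config = cfg)
    test_imgs <- cohort$images[idx[[k]]$test]
    preds <- vapply(test_imgs, function(img)
      classify_image_vote(model, img, vote)$label, 0L)
    recs[[k]] <- records_df(vapply(test_imgs, `[[`, "", "image_id"),
                            vapply(test_imgs, `[[`, 0L, "label"),
                            preds, m$name, k)
  }
  do.call(rbind, recs)
}

run_cnn_svm_method <- function(m, cohort, plan, seed) {
  arch <- m$arch %||% "CNN-05"
  tap <- m$tap %||% "PFCL"
  stride <- m$stride %||% 32L
  tc_args <- m$train %||% list()
  counts <- m$per_class_counts %||% list(healthy = 6, abnormal = 6)
  P <- scratch_arch(arch)$input[1]
  idx <- fold_index(cohort, plan)
  patch_vectors <- function(model, img) {
    ps <- grid_patches(img, P, stride)
    t(vapply(seq_len(nrow(ps$meta)), function(i)
      extract_layer_vector(model,
                           normalize_patch(ps$pixels[, , , i, drop = TRUE]),
                           tap),
      numeric(model$arch$fc[model$arch$taps[[tap]]])))
  }
  recs <- list()
  for (k in seq_along(idx)) {
    fold_seed <- derive_seed(seed, paste0("fold/", m$name, "/", k))
    train_co <- sub_cohort(cohort, idx[[k]]$train)
    patches <- sample_balanced(train_co, P, counts, seed = fold_seed)
    cfg <- do.call(train_config, c(tc_args, list(seed = fold_seed)))
    model <- build_model(scratch_arch(arch), seed = fold_seed)
    model <- train_cnn(model, patches, config = cfg)
    Xtr <- do.call(rbind, lapply(train_co$images, patch_vectors,
                                 model = model))
    n_per <- nrow(Xtr) / length(train_co$images)
    ytr <- rep(vapply(train_co$images, `[[`, 0L, "label"), each = n_per)
    clf <- train_linear_svm(Xtr, ytr, C = m$C %||% 1)
    test_imgs <- cohort$images[idx[[k]]$test]
    preds <- vapply(test_imgs, function(img) {
      v <- predict_svm(clf, patch_vectors(model, img))
      as.integer(2L * sum(v == 1L) >= length(v))
    }, 0L)
    recs[[k]] <- records_df(vapply(test_imgs, `[[`, "", "image_id"),
                            vapply(test_imgs, `[[`, 0L, "label"),
                            preds, m$name, k)
  }
  do.call(rbind, recs)
}

run_feature_svm_method <- function(m, cohort, plan, seed) {
  extractors <- lapply(unlist(m$features), make_extractor,
                       params = m$params %||% list(),
                       seed = derive_seed(seed, paste0("extract/", m$name)))
  X <- cohort_feature_matrix(cohort, extractors)
  y <- cohort$metadata$label
  idx <- fold_index(cohort, plan)
  recs <- list()
  for (k in seq_along(idx)) {
    tr <- idx[[k]]$train; te <- idx[[k]]$test
    clf <- train_linear_svm(X[tr, , drop = FALSE], y[tr], C = m$C %||% 1)
    preds <- predict_svm(clf, X[te, , drop = FALSE])
    recs[[k]] <- records_df(cohort$metadata$image_id[te], y[te], preds,
                            m$name, k)
  }
  do.call(rbind, recs)
}

#' Run a full config-driven classification experiment
#'
#' Generates (or reads) a cohort, builds the fold plan, runs every
#' configured method, and aggregates per-image prediction records into an
#' accuracy table and pairwise McNemar comparison matrices.  Reruns with
#' the same config and seeds reproduce the report byte-for-byte.
#'
#' The config (a named list, or a path to a YAML file) understands:
#' \describe{
#'   \item{cohort}{Arguments to [cohort_spec()], or `list(directory = ...)`
#'     to read a written cohort.}
#'   \item{folds}{`list(strategy = "lopo")` or `list(strategy = "grouped",
#'     sizes = c(...), seed = ...)`.}
#'   \item{methods}{List of method descriptions; each needs `name` and
#'     `type` (one of `"cnn_scratch"`, `"cnn_svm"`, `"feature_svm"`), plus
#'     type-specific fields (`arch`, `train`, `vote`, `per_class_counts`,
#'     `augment`; `features` such as `"mb_lbp"`, `"gwt_weibull"`,
#'     `"offshelf:VGG-VD16:PFCL"`; `tap`, `stride`, `C`).}
#'   \item{alpha}{Significance level(s) for the comparison matrices.}
#'   \item{seed}{Master seed for all per-fold substreams.}
#'   \item{output_dir}{Optional directory for CSV/JSON report files.}
#' }
#'
#' @param config Named list or YAML file path.
#' @return A `polyp_report`: list with `records`, `accuracy` (data frame),
#'   `comparisons` (one `comparison_matrix` per alpha), `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  seed <- config$seed %||% 1L

  cohort <- if (!is.null(config$cohort$directory)) {
    read_cohort(config$cohort$directory)
  } else {
    generate_cohort(do.call(cohort_spec, config$cohort %||% list()))
  }

  plan <- if ((config$folds$strategy %||% "lopo") == "lopo") {
    lopo_folds(cohort)
  } else {
    grouped_kfold(cohort, unlist(config$folds$sizes),
                  seed = config$folds$seed %||% seed)
  }

  records <- list()
  for (m in config$methods) {
    records[[m$name]] <- switch(m$type,
      cnn_scratch = run_cnn_scratch_method(m, cohort, plan, seed),
      cnn_svm = run_cnn_svm_method(m, cohort, plan, seed),
      feature_svm = run_feature_svm_method(m, cohort, plan, seed))
  }

  acc <- data.frame(
    method = names(records),
    accuracy = vapply(records, accuracy, 0),
    stringsAsFactors = FALSE, row.names = NULL)

  alphas <- config$alpha %||% c(0.01, 0.05)
  comparisons <- if (length(records) >= 2L) {
    setNames(lapply(alphas, function(a) significance_matrix(records, a)),
             paste0("alpha_", alphas))
  } else list()

  report <- structure(list(records = records, accuracy = acc,
                           comparisons = comparisons, config = config),
                      class = "polyp_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.polyp_report <- function(x, ...) {
  cat("Pipeline report:", length(x$records), "methods,",
      nrow(x$records[[1]]), "images\n")
  print(transform(x$accuracy, accuracy = round(accuracy, 4)))
  for (nm in names(x$comparisons)) {
    cm <- x$comparisons[[nm]]
    cat("\nSignificant pairs at alpha =", cm$alpha, ":",
        sum(cm$significant[upper.tri(cm$significant)]), "\n")
  }
  invisible(x)
}

#' Persist a pipeline report as CSV tables and a JSON summary
#'
#' Writes `records.csv` (all per-image predictions), `accuracy.csv`,
#' per-alpha p-value and significance-flag CSVs, and `summary.json`.
#'
#' @param report A `polyp_report`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write.csv(do.call(rbind, c(report$records, make.row.names = FALSE)),
            file.path(directory, "records.csv"), row.names = FALSE)
  write.csv(report$accuracy, file.path(directory, "accuracy.csv"),
            row.names = FALSE)
  for (nm in names(report$comparisons)) {
    cm <- report$comparisons[[nm]]
    write.csv(cm$p, file.path(directory, paste0("mcnemar_p_", nm, ".csv")))
    write.csv(cm$significant,
              file.path(directory, paste0("mcnemar_flags_", nm, ".csv")))
  }
  jsonlite::write_json(
    list(accuracy = report$accuracy,
         n_images = nrow(report$records[[1]]),
         methods = names(report$records)),
    file.path(directory, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(directory)
}
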