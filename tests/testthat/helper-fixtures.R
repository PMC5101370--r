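# Fixture builders shared across test files.  Everything is generated in
# code at test time; nothing is read from disk.

# A labeled image with given pixels (defaults to a reproducible random
# texture).
make_image <- function(side = 16, id = "img1", patient = "P001", label = 0L,
                       pixels = NULL, seed = 1) {
  if (is.null(pixels)) {
    set.seed(seed)
    pixels <- array(runif(side * side * 3), c(side, side, 3))
  }
  polypatch:::new_labeled_image(pixels, id, patient, label, "synthetic")
}

# A cohort of n tiny random images spread over n_patients patients with a
# prescribed number of abnormal images.
make_tiny_cohort <- function(n = 6, n_patients = 3, side = 16, n_abnormal = 3,
                             seed = 1) {
  labels <- c(rep(1L, n_abnormal), rep(0L, n - n_abnormal))
  imgs <- lapply(seq_len(n), function(i)
    make_image(side, sprintf("I%03d", i),
               sprintf("P%03d", (i - 1) %% n_patients + 1),
               labels[i], seed = seed + i))
  polypatch:::new_cohort(imgs)
}

# Small architecture used wherever a full preset would be wastefully slow.
toy_arch <- function(fc = c(6L, 2L), side = 8L) {
  arch_spec(c(side, side, 3L),
            list(list(n = 4L, k = 3L,
                      pool = list(type = "max", size = 2L, stride = 2L)),
                 list(n = 5L, k = 2L)),
            fc, classifier = TRUE, name = "toy")
}
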