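# Augmentation, patch extraction, balanced sampling, normalization,
# bicubic resizing.

test_that("augment_image returns 7 transforms with fixed order and ids", {
  img <- make_image(16, label = 1L)
  out <- augment_image(img)
  expect_length(out, 7)
  tags <- c("hf", "vf", "r90r", "r90l", "r90r_hf", "r90l_hf", "hf_vf")
  expect_identical(vapply(out, `[[`, "", "image_id"),
                   paste0(img$image_id, "_", tags))
  for (o in out) {
    expect_identical(dim(o$pixels), dim(img$pixels))
    expect_identical(o$label, img$label)
    expect_identical(o$patient_id, img$patient_id)
    # every transform permutes pixels: the value multiset is preserved
    expect_identical(sort(as.numeric(o$pixels)),
                     sort(as.numeric(img$pixels)))
  }
})

test_that("augmentations are identity on constant images and pairwise
           distinct on an asymmetric image", {
  const <- make_image(8, pixels = array(0.5, c(8, 8, 3)))
  for (o in augment_image(const))
    expect_identical(o$pixels, const$pixels)

  # a single bright corner pixel breaks every symmetry
  px <- array(0, c(8, 8, 3))
  px[1, 1, ] <- 1
  px[2, 1, 1] <- 0.5  # break the hflip/rot ambiguity on the diagonal
  img <- make_image(8, pixels = px)
  outs <- c(list(img$pixels), lapply(augment_image(img), `[[`, "pixels"))
  for (i in seq_along(outs))
    for (j in seq_along(outs))
      if (i < j) expect_false(identical(outs[[i]], outs[[j]]))
})

test_that("non-square images are rejected by augmentation", {
  img <- polypatch:::new_labeled_image(array(0.1, c(8, 10, 3)),
                                       "bad", "P1", 0L, "m")
  expect_error(suppressWarnings(augment_image(img)), "square")
})

test_that("augment_cohort multiplies counts by 8 and keeps patients", {
  co <- make_tiny_cohort(n = 3, n_patients = 2, side = 8)
  aug <- augment_cohort(co)
  expect_identical(nrow(aug$metadata), 24L)
  expect_identical(table(aug$metadata$patient_id),
                   table(co$metadata$patient_id) * 8L)
  empty <- polypatch:::new_cohort(list())
  expect_identical(nrow(augment_cohort(empty)$metadata), 0L)
})

test_that("grid patch counts follow the closed-interval stride convention", {
  img <- make_image(256, seed = 3)
  for (cs in list(c(5, 676), c(20, 49), c(32, 25), c(48, 9))) {
    ps <- grid_patches(img, 128, cs[1], materialize = FALSE)
    expect_identical(nrow(ps$meta), as.integer(cs[2]))
  }
  # offsets match brute-force enumeration of all valid stride multiples
  ps <- grid_patches(img, 128, 48, materialize = FALSE)
  valid <- seq(0, 256 - 128, by = 48)
  brute <- expand.grid(col = valid, row = valid)[, c("row", "col")]
  brute <- brute[order(brute$row, brute$col), ]
  expect_equal(ps$meta$row, brute$row, ignore_attr = TRUE)
  expect_equal(ps$meta$col, brute$col, ignore_attr = TRUE)
})

test_that("grid count formula matches exhaustive enumeration on small sides", {
  for (side in c(12L, 17L, 32L)) {
    img <- make_image(side)
    for (P in c(4L, 7L, side)) {
      for (s in c(1L, 3L, 5L)) {
        ps <- grid_patches(img, P, s, materialize = FALSE)
        brute <- 0L
        for (r in 0:(side - P)) for (cc in 0:(side - P))
          if (r %% s == 0 && cc %% s == 0) brute <- brute + 1L
        expect_identical(nrow(ps$meta), brute)
        expect_true(all(ps$meta$row + P <= side & ps$meta$col + P <= side))
      }
    }
  }
})

test_that("side == P yields the single patch at the origin and P > side errors", {
  img <- make_image(16)
  ps <- grid_patches(img, 16, 4)
  expect_identical(nrow(ps$meta), 1L)
  expect_identical(c(ps$meta$row, ps$meta$col), c(0L, 0L))
  expect_identical(ps$pixels[, , , 1], img$pixels)
  expect_error(grid_patches(img, 17, 1), "exceeds")
  expect_error(random_patches(img, 17, 5), "exceeds")
})

test_that("random patches are in bounds, seeded, and uniform over offsets", {
  img <- make_image(64)
  ps1 <- random_patches(img, 32, 25, seed = 7)
  ps2 <- random_patches(img, 32, 25, seed = 7)
  expect_identical(ps1$meta, ps2$meta)
  expect_identical(nrow(ps1$meta), 25L)
  expect_true(all(ps1$meta$row + 32 <= 64 & ps1$meta$col + 32 <= 64))
  expect_identical(nrow(random_patches(img, 32, 0)$meta), 0L)

  # chi-square uniformity over the valid offset grid at alpha = 0.01
  big <- random_patches(make_image(19), 4, 10000, seed = 5,
                        materialize = FALSE)
  for (ax in c("row", "col")) {
    tab <- tabulate(big$meta[[ax]] + 1L, nbins = 16)
    p <- chisq.test(tab)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("balanced sampling equalizes per-class patch totals", {
  # 1 healthy + 3 abnormal images, counts inversely proportional to the
  # class image counts -> equal totals
  co <- make_tiny_cohort(n = 4, n_patients = 2, side = 16, n_abnormal = 3)
  ps <- sample_balanced(co, 8, c(healthy = 75, abnormal = 25), seed = 2)
  expect_identical(sum(ps$meta$label == 0), 75L)
  expect_identical(sum(ps$meta$label == 1), 75L)
  expect_identical(dim(ps$pixels)[4], 150L)

  one <- polypatch:::new_cohort(list(make_image(16, label = 1L)))
  expect_identical(nrow(suppressWarnings(
    sample_balanced(one, 8, c(healthy = 5, abnormal = 5),
                    seed = 1))$meta), 5L)
  expect_warning(sample_balanced(one, 8, c(healthy = 5, abnormal = 5),
                                 seed = 1), "healthy")
})

test_that("patch normalization gives mean 0 / population sd 1 and handles
           degenerate inputs", {
  set.seed(4)
  p <- array(runif(8 * 8 * 3), c(8, 8, 3))
  np <- normalize_patch(p)
  expect_lt(abs(mean(np)), 1e-6)
  expect_lt(abs(sqrt(mean((np - mean(np))^2)) - 1), 1e-6)

  expect_identical(normalize_patch(array(0.7, c(4, 4, 3))),
                   array(0, c(4, 4, 3)))
  two <- array(rep(c(0, 1), each = 24), c(4, 4, 3))
  expect_identical(sort(unique(as.numeric(normalize_patch(two)))),
                   c(-1, 1))
})

test_that("bicubic resize hits the target size, is the identity at equal
           size, and reproduces linear ramps", {
  img <- make_image(64, seed = 6)
  out <- resize_bicubic(img, 56)
  expect_identical(dim(out$pixels), c(56L, 56L, 3L))
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))

  same <- resize_bicubic(img$pixels, 64)
  expect_lt(max(abs(same - img$pixels)), 1e-6)

  ramp <- array(rep(seq(0.1, 0.9, length.out = 64), each = 64),
                c(64, 64, 3))
  res <- resize_bicubic(ramp, 56)
  expected <- (seq_len(56) - 0.5) * 64 / 56 + 0.5
  expected <- 0.1 + (expected - 1) * (0.9 - 0.1) / 63
  for (ch in 1:3)
    expect_lt(max(abs(res[1, , ch] - expected)), 1e-3)
  expect_error(resize_bicubic(img, 3), "target")
})

test_that("patches inherit label and patient through augment + grid", {
  co <- make_tiny_cohort(n = 2, n_patients = 2, side = 16, n_abnormal = 1)
  aug <- augment_cohort(co)
  for (img in aug$images) {
    ps <- grid_patches(img, 8, 8, materialize = FALSE)
    expect_true(all(ps$meta$label == img$label))
    expect_true(all(ps$meta$patient_id == img$patient_id))
  }
})
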