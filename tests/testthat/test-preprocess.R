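test_that("fold threshold halves the first predominant peak location", {
  cfg <- fold_threshold_config()
  # single narrow mode at L* = 40
  set.seed(2)
  L1 <- matrix(40 + runif(4000, -0.4, 0.4), 50, 80)
  expect_equal(fold_threshold(L1, cfg), 20, tolerance = 0.5)
  # constant raster: sole peak at its own value
  expect_equal(fold_threshold(matrix(60, 10, 10), cfg), 30)
  # trimodal wall/outside/lumen profile: first peak wins
  L3 <- matrix(c(rnorm(3000, 35, 1.2), rnorm(2500, 80, 1.2),
                 rnorm(2500, 95, 1)), 80, 100)
  expect_equal(fold_threshold(L3, cfg), 17.5, tolerance = 0.5)
})

test_that("fold threshold ignores subdominant early bumps", {
  # a tiny bump at L*=10 below the prominence cutoff must be skipped
  set.seed(3)
  L <- matrix(c(rnorm(60, 10, 0.5), rnorm(5000, 55, 1.5)), 46, 110)
  t <- fold_threshold(L, fold_threshold_config(prominence_fraction = 0.25))
  expect_equal(t, 27.5, tolerance = 0.6)
})

test_that("fold detection is an exact lightness cut", {
  L <- matrix(80, 6, 6)
  lab <- lab_from_matrix(L)
  expect_equal(pixel_area(detect_folds(lab, 20)), 0)
  L[3, 4] <- 5
  m <- detect_folds(lab_from_matrix(L), 20)
  expect_equal(pixel_area(m), 1)
  expect_true(m[3, 4])
  expect_equal(attr(m, "role"), "defect")
})

test_that("blood color mask selects exactly the in-ball pixels", {
  L <- matrix(c(35, 35, 60), 1, 3)
  a <- matrix(c(45, 44, 0), 1, 3)
  b <- matrix(c(25, 25, 0), 1, 3)
  lab <- lab_from_matrix(L, a, b)
  m0 <- detect_blood(lab, color_mask(center = c(35, 45, 25), radius = 0))
  expect_equal(which(m0), 1L)
  mall <- detect_blood(lab, color_mask(center = c(35, 45, 25), radius = 1e3))
  expect_equal(pixel_area(mall), 3)
})

test_that("blood blobs painted near the mask center are recovered", {
  sp <- vessel_spec(smf_fraction = 0.4, n_folds = 0, n_blood = 3, n_dust = 0,
                    color_noise_sd = 2, seed = 21)
  g <- generate_vessel_image(sp)
  lab <- rgb_to_lab(g$image)
  m <- detect_blood(lab, color_mask())
  blob <- g$truth$blood_mask
  expect_gt(sum(m & blob) / sum(blob), 0.99)
})

test_that("defect removal zeroes flagged pixels and marks them invalid", {
  L <- matrix(runif(30, 40, 80), 5, 6)
  lab <- lab_from_matrix(L)
  none <- remove_defects(lab, list())
  expect_equal(none$L, L)
  expect_true(all(none$valid))

  all_mask <- binary_mask(matrix(TRUE, 5, 6), "defect")
  gone <- remove_defects(lab, list(all_mask))
  expect_true(all(gone$L == 0))
  expect_false(any(gone$valid))

  one <- matrix(FALSE, 5, 6); one[2, 3] <- TRUE
  single <- remove_defects(lab, list(binary_mask(one, "defect")))
  expect_equal(single$L[2, 3], 0)
  expect_false(single$valid[2, 3])
  expect_equal(single$L[-which(one)], L[-which(one)])

  expect_error(remove_defects(lab, list(binary_mask(matrix(FALSE, 2, 2), "defect"))),
               "dimension")
})

test_that("contrast stretch maps the valid range onto [0, 100]", {
  L <- matrix(c(20, 45, 70, 33), 2, 2)
  out <- contrast_stretch(L)
  expect_equal(out[1, 1], 0)    # Lmin -> 0
  expect_equal(out[1, 2], 100)  # Lmax -> 100
  expect_equal(out[2, 1], round(100 * 25 / 50))  # direct evaluation
  expect_error(contrast_stretch(matrix(7, 3, 3)), "constant")
})

test_that("contrast stretch is monotone and ignores invalid pixels", {
  set.seed(8)
  L <- matrix(runif(200, 10, 90), 10, 20)
  out <- contrast_stretch(L)
  o <- order(as.numeric(L))
  expect_true(all(diff(out[o]) >= 0))

  # zeroed defect pixels must not drag Lmin to 0
  valid <- matrix(TRUE, 10, 20); valid[1, 1] <- FALSE
  L2 <- L; L2[1, 1] <- 0
  out2 <- contrast_stretch(L2, valid)
  expect_equal(min(out2[valid]), 0)
  expect_equal(max(out2[valid]), 100)
  expect_equal(out2[1, 1], 0)
})

test_that("Otsu separates a two-valued raster strictly between its values", {
  x <- matrix(c(rep(0.2, 60), rep(0.8, 40)), 10, 10)
  T <- otsu_threshold(x)
  expect_gt(T, 0.2)
  expect_lt(T, 0.8)
  expect_error(otsu_threshold(matrix(0.5, 4, 4)), "constant")
})

test_that("Otsu equals the brute-force between-class-variance maximizer", {
  set.seed(11)
  for (i in 1:8) {
    n <- sample(8:40, 1)
    x <- matrix(runif(n * n), n, n)
    if (i %% 2 == 0) x <- matrix(sample(seq(0, 1, by = 0.05), n * n, TRUE), n, n)
    expect_equal(otsu_threshold(x), naive_otsu(x))
  }
})

test_that("Otsu lands between the modes of a bimodal mixture", {
  set.seed(12)
  v <- c(rnorm(2000, 0.3, 0.05), rnorm(2000, 0.8, 0.05))
  x <- matrix(pmin(pmax(v, 0), 1), 40, 100)
  T <- otsu_threshold(x)
  expect_gt(T, 0.45)
  expect_lt(T, 0.65)
})

test_that("Otsu agrees with the EBImage implementation on shared data", {
  skip_if_not_installed("EBImage")
  set.seed(13)
  x <- matrix(pmin(pmax(c(rnorm(1500, 0.35, 0.06), rnorm(2500, 0.75, 0.06)), 0), 1),
              40, 100)
  T_eb <- EBImage::otsu(EBImage::Image(t(x)), range = c(0, 1), levels = 256)
  expect_lt(abs(otsu_threshold(x) - T_eb), 2 / 255)
})

test_that("pixel area counts foreground pixels", {
  expect_equal(pixel_area(matrix(FALSE, 7, 3)), 0)
  m <- matrix(FALSE, 5, 5); m[c(1, 3, 7, 20, 25)] <- TRUE
  expect_equal(pixel_area(m), 5)
  set.seed(14)
  r <- matrix(runif(600) < 0.4, 20, 30)
  expect_equal(pixel_area(r), sum(vapply(seq_len(20), function(i) sum(r[i, ]), 0)))
})

test_that("wall cleanup keeps a clean annulus untouched", {
  ann <- annulus_mask()
  wr <- clean_wall_mask(binary_mask(ann, "wall"))
  expect_equal(unclass(wr$mask)[, ], ann, ignore_attr = TRUE)
  expect_equal(wr$A_TOT, sum(ann))
})

test_that("wall cleanup removes specks and fills pinholes", {
  ann <- annulus_mask()
  dirty <- ann
  set.seed(15)
  # small specks in lumen and exterior
  h <- nrow(ann)
  rows <- matrix(seq_len(h), h, h)
  cols <- matrix(seq_len(h), h, h, byrow = TRUE)
  rr <- sqrt((rows - (h + 1) / 2)^2 + (cols - (h + 1) / 2)^2)
  outside <- which(!ann & (rr < 10 | rr > 34))
  for (p in sample(outside, 20)) dirty[p] <- TRUE
  # 3-pixel pinholes inside the wall
  wall_idx <- which(ann & rr > 18 & rr < 26)
  holes <- sample(wall_idx, 3)
  dirty[holes] <- FALSE
  dirty[holes + 1L] <- FALSE
  dirty[holes - 1L] <- FALSE

  wr <- clean_wall_mask(binary_mask(dirty, "wall"))
  expect_equal(unclass(wr$mask)[, ], ann, ignore_attr = TRUE)
  expect_equal(wr$A_TOT, sum(ann))
  expect_lte(wr$A_TOT, length(ann))
})

test_that("wall cleanup fails loudly when nothing clusters", {
  expect_error(clean_wall_mask(binary_mask(matrix(FALSE, 30, 30), "wall")),
               "segmentation failure")
  one <- matrix(FALSE, 30, 30); one[5, 5] <- TRUE
  expect_error(clean_wall_mask(binary_mask(one, "wall")),
               "segmentation failure")
})
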