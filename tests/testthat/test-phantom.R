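test_that("crop rendering is deterministic and latent-sensitive", {
  lat0 <- phantom_latents(0, 0, 0, 0)
  lat1 <- phantom_latents(1, 1, 1, 1)
  a <- render_crop(lat0, grid_shape = tiny_grid, seed = 3, noise_sd = 0.05)
  b <- render_crop(lat0, grid_shape = tiny_grid, seed = 3, noise_sd = 0.05)
  expect_identical(unclass(a), unclass(b))
  d <- render_crop(lat1, grid_shape = tiny_grid, seed = 3, noise_sd = 0.05)
  expect_gt(mean(abs(unclass(d) - unclass(a))), 0.05) # beyond the noise floor
  expect_true(all(a >= 0 & a <= 1))
  expect_error(render_crop(lat0, grid_shape = c(4L, 4L, 4L)), "grid_shape")
  expect_error(phantom_latents(t1 = 1.2), "\\[0, 1\\]")
})

test_that("grooves darken their wedge masks monotonically with depth latents", {
  gs <- c(20L, 16L, 12L)
  wedge2 <- ihiscore:::sulcus_wedge_mask(gs, "collateral")
  wedge5 <- ihiscore:::sulcus_wedge_mask(gs, "fusiform")
  means2 <- means5 <- numeric(0)
  for (t in seq(0, 1, by = 0.25)) {
    c2 <- render_crop(phantom_latents(t2 = t), grid_shape = gs)
    c5 <- render_crop(phantom_latents(t5 = t), grid_shape = gs)
    means2 <- c(means2, mean(c2[wedge2]))
    means5 <- c(means5, mean(c5[wedge5]))
  }
  expect_true(all(diff(means2) <= 1e-12))
  expect_true(all(diff(means5) <= 1e-12))
  expect_lt(means2[5], means2[1]) # strictly darker at full depth
  expect_lt(means5[5], means5[1])
})

test_that("verticality and medial-position latents move the body as designed", {
  gs <- c(24L, 20L, 16L)
  # t1: the z-spread of bright body voxels grows as the body turns vertical
  zspread <- vapply(c(0, 0.5, 1), function(t) {
    cr <- render_crop(phantom_latents(t1 = t, t3 = 0), grid_shape = gs,
                      anatomy = list(roundness_gain = 0))
    idx <- which(unclass(cr) > 0.75, arr.ind = TRUE)
    stats::sd(idx[, 3])
  }, numeric(1))
  expect_true(all(diff(zspread) > 0))
  # t3: the intensity-weighted x centroid moves medially
  xcent <- vapply(c(0, 0.5, 1), function(t) {
    cr <- render_crop(phantom_latents(t3 = t), grid_shape = gs)
    idx <- which(unclass(cr) > 0.75, arr.ind = TRUE)
    mean(idx[, 1])
  }, numeric(1))
  expect_true(all(diff(xcent) > 0))
})

test_that("latents map to on-grid truth scores monotonically", {
  expect_equal(latents_to_scores(phantom_latents(0.5, 0.5, 0.5, 0.5)),
               c(C1 = 1.0, C2 = 1.0, C3 = 1.0, C5 = 1))
  expect_equal(latents_to_scores(phantom_latents(1, 1, 1, 1)),
               c(C1 = 2, C2 = 2, C3 = 2, C5 = 2))
  expect_equal(latents_to_scores(phantom_latents(0.3, 0.3, 0.3, 0.3)),
               c(C1 = 0.5, C2 = 0.5, C3 = 0.5, C5 = 1))
  set.seed(5)
  for (k in 1:20) {
    a <- sort(stats::runif(2))
    la <- latents_to_scores(phantom_latents(a[1], a[1], a[1], a[1]))
    lb <- latents_to_scores(phantom_latents(a[2], a[2], a[2], a[2]))
    expect_true(all(lb >= la))
  }
})

test_that("rater simulation perturbs by one grid step and respects bounds", {
  truth <- c(C1 = 0, C2 = 0, C3 = 0, C5 = 0)
  expect_identical(simulate_rater(truth, flip_prob = 0, seed = 1), truth)
  flipped <- simulate_rater(truth, flip_prob = 1, seed = 1)
  expect_equal(unname(flipped), c(0.5, 0.5, 0.5, 1)) # only upward moves at the floor
  top <- c(C1 = 2, C2 = 2, C3 = 2, C5 = 2)
  expect_equal(unname(simulate_rater(top, flip_prob = 1, seed = 2)),
               c(1.5, 1.5, 1.5, 1))
  set.seed(9)
  grids <- random_scores(30, seed = 3)
  for (i in seq_len(nrow(grids))) {
    sc <- c(C1 = grids$c1[i], C2 = grids$c2[i], C3 = grids$c3[i], C5 = grids$c5[i])
    out <- simulate_rater(sc, flip_prob = 0.5, seed = i)
    for (cr in ihi_criteria()) {
      expect_true(out[[cr]] %in% criterion_grid(cr))
      expect_lte(abs(out[[cr]] - sc[[cr]]), criterion_step(cr) + 1e-12)
    }
  }
})

test_that("default rater noise lands composite ICC in the inter-rater band", {
  co <- generate_cohort(cohort_spec("cal", 500, grid_shape = c(8L, 8L, 8L),
                                    noise_sd = 0, blur_fwhm = 0), seed = 17)
  tl <- co$ratings_truth[co$ratings_truth$hemisphere == "left", ]
  ol <- co$ratings_observed[co$ratings_observed$hemisphere == "left", ]
  r <- icc(tl$composite, ol$composite)
  expect_gte(r, 0.70)
  expect_lte(r, 0.85)
})

test_that("cohort generation is reproducible and prevalence-controlled", {
  co1 <- generate_cohort(cohort_spec("rep", 12, grid_shape = tiny_grid), seed = 5)
  co2 <- generate_cohort(cohort_spec("rep", 12, grid_shape = tiny_grid), seed = 5)
  expect_identical(co1$ratings_observed, co2$ratings_observed)
  expect_identical(unclass(co1$crops$left[[3]]), unclass(co2$crops$left[[3]]))

  one <- generate_cohort(cohort_spec("one", 1, grid_shape = tiny_grid), seed = 2)
  expect_equal(nrow(one$ratings_truth), 2) # both hemispheres
  expect_length(one$crops$right, 1)

  big <- generate_cohort(cohort_spec("prev", 2000, target_prevalence_left = 0.21,
                                     grid_shape = c(8L, 8L, 8L)), seed = 11)
  tl <- big$ratings_truth[big$ratings_truth$hemisphere == "left", ]
  p_hat <- mean(tl$ihi_flag)
  half_width <- 1.96 * sqrt(0.21 * 0.79 / 2000)
  expect_lt(abs(p_hat - 0.21), half_width)
  tr <- big$ratings_truth[big$ratings_truth$hemisphere == "right", ]
  expect_lt(mean(tr$ihi_flag), p_hat) # right-hemisphere analogue is rarer
})

test_that("truth records satisfy the rating-protocol invariants", {
  co <- small_cohort()
  tt <- co$ratings_truth
  expect_equal(tt$composite, tt$c1 + tt$c2 + tt$c3 + tt$c5)
  expect_true(all(tt$c1 %in% criterion_grid("C1")))
  expect_true(all(tt$c5 %in% criterion_grid("C5")))
  expect_true(all(tt$composite >= 0 & tt$composite <= 8))
  expect_identical(tt$ihi_flag, tt$composite >= 4)
  oo <- co$ratings_observed
  expect_true(all(oo$c2 %in% criterion_grid("C2")))
  expect_equal(oo$composite, oo$c1 + oo$c2 + oo$c3 + oo$c5)
})

test_that("unattainable prevalence targets are rejected", {
  expect_error(cohort_spec("bad", 10, target_prevalence_left = 1.2), "\\[0, 1\\]")
  expect_error(generate_cohort(cohort_spec("bad", 10, target_prevalence_left = 1,
                                           grid_shape = tiny_grid), seed = 1),
               "unattainable")
})

test_that("phantom datasets round-trip through NIfTI and TSV", {
  co <- generate_cohort(cohort_spec("io", 2, grid_shape = tiny_grid), seed = 8)
  dir <- tempfile("phantom_io_")
  on.exit(unlink(dir, recursive = TRUE))
  write_phantom_dataset(co, dir)
  expect_true(file.exists(file.path(dir, "ratings_observed.tsv")))
  vol <- load_volume(file.path(dir, "io_0001_left.nii.gz"))
  expect_equal(as.array(vol), unclass(co$crops$left[[1]]),
               ignore_attr = TRUE, tolerance = 1e-6)
  back <- read_ratings(file.path(dir, "ratings_truth.tsv"))
  expect_equal(back$composite, co$ratings_truth$composite)
})
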