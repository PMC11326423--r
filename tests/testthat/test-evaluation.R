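test_that("ICC is exact on closed-form cases and penalizes bias", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_equal(icc(a, a), 1)
  b <- c(1.5, 1.8, 3.4, 3.9, 5.2, 6.4)
  expect_equal(icc(a, b), icc_oracle(a, b), tolerance = 1e-10)
  expect_equal(icc(a, b, "icc3_1"), icc_oracle(a, b, "icc3_1"), tolerance = 1e-10)
  shifted <- a + 3
  expect_lt(icc(a, shifted), icc(a, shifted, "icc3_1")) # absolute agreement penalizes offset
  expect_equal(icc(a, shifted, "icc3_1"), 1, tolerance = 1e-12)
  expect_error(icc(rep(1, 6), rep(1, 6)), "zero total variance")
  expect_error(icc(1:4, 1:4), "at least 5")
  expect_error(icc(1:6, 1:5), "paired")
})

test_that("kappa matches its closed forms and rejects off-grid input", {
  a <- rep(c(0, 1), c(50, 50))
  b <- c(rep(0, 45), rep(1, 5), rep(1, 45), rep(0, 5)) # table [[45,5],[5,45]]
  expect_equal(cohen_kappa(a, b, weighting = "none", categories = c(0, 1)), 0.8)
  g <- criterion_grid("C1")
  set.seed(2)
  x <- sample(g, 80, TRUE)
  expect_equal(cohen_kappa(x, x, categories = g), 1)
  expect_error(cohen_kappa(c(0, 0.3), c(0, 0.5), categories = g), "grid")
  expect_error(cohen_kappa(rep(0, 10), rep(0, 10), categories = g),
               "single identical category")
  # independent raters at large n are chance-level
  set.seed(31)
  xa <- sample(g, 2000, TRUE)
  xb <- sample(g, 2000, TRUE)
  expect_lt(abs(cohen_kappa(xa, xb, "quadratic", g)), 0.1)
  expect_lt(abs(cohen_kappa(xa, xb, "none", g)), 0.1)
})

test_that("ICC and kappa agree with brute-force oracles on random tables", {
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(6:25, 1)
    a <- stats::rnorm(n)
    b <- 0.6 * a + stats::rnorm(n, 0, 0.8)
    variant <- sample(c("icc2_1", "icc3_1"), 1)
    expect_equal(icc(a, b, variant), icc_oracle(a, b, variant), tolerance = 1e-10)

    cr <- sample(ihi_criteria(), 1)
    g <- criterion_grid(cr)
    xa <- sample(g, n, TRUE)
    xb <- round_prediction(xa + stats::rnorm(n, 0, 0.6), cr)
    w <- sample(c("none", "quadratic"), 1)
    if (length(unique(c(xa, xb))) > 1) {
      expect_equal(cohen_kappa(xa, xb, w, g), kappa_oracle(xa, xb, w, g),
                   tolerance = 1e-10)
    }
  }
})

test_that("bootstrap summaries are deterministic and degenerate-safe", {
  agree <- function(a, b) mean(a == b)
  a <- rep(c(0, 1, 2), 10)
  r1 <- bootstrap_metric(agree, a, a, n_boot = 50, seed = 9)
  expect_equal(r1$boot_se, 0)
  expect_equal(r1$ci_lower, r1$ci_upper)
  expect_equal(r1$point, 1)
  r2 <- bootstrap_metric(agree, a, a, n_boot = 50, seed = 9)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$indices, r2$indices)
  set.seed(14)
  for (k in 1:200) {
    n <- sample(10:40, 1)
    t <- stats::rnorm(n)
    p <- t + stats::rnorm(n)
    r <- bootstrap_metric(function(x, y) stats::cor(x, y), t, p,
                          n_boot = 30, seed = k)
    expect_lte(r$ci_lower, r$ci_upper)
  }
  expect_error(bootstrap_metric(function(x, y) stop("nope"), 1:10, 1:10,
                                n_boot = 20, seed = 1), "more than half")
})

test_that("paired comparisons reuse identical resamples and behave at the ends", {
  set.seed(15)
  truth <- stats::rnorm(80, 4, 2)
  pa <- truth + stats::rnorm(80, 0, 1)
  cmp0 <- compare_methods(truth, pa, pa, icc, n_boot = 60, seed = 3, m_tests = 4)
  expect_identical(cmp0$metric_a$indices, cmp0$metric_b$indices)
  expect_true(all(cmp0$differences == 0))
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p_adjusted, 1)
  expect_false(cmp0$significant)

  pb <- truth + stats::rnorm(80, 0, 8) # much worse method
  cmp1 <- compare_methods(truth, pa, pb, icc, n_boot = 100, seed = 3, m_tests = 4)
  expect_gt(cmp1$mean_difference, 0)
  expect_true(cmp1$significant) # survives Bonferroni
  expect_equal(cmp1$p_adjusted, min(1, 4 * cmp1$p))
  expect_error(compare_methods(truth, pa[1:10], pb, icc), "align")
})

test_that("adding label noise degrades mean ICC monotonically", {
  sds <- c(0.2, 0.8, 2.5)
  mean_icc <- vapply(sds, function(s) {
    mean(vapply(1:5, function(seed) {
      set.seed(seed)
      t <- stats::rnorm(120, 4, 2)
      icc(t, t + stats::rnorm(120, 0, s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_icc) < 0.02)) # non-increasing up to sampling slack
  expect_lt(mean_icc[3], mean_icc[1])
})

test_that("evaluate_run rounds, joins and reports per hemisphere and cohort", {
  co <- small_cohort()
  truth <- co$ratings_observed
  # perfect predictions, given as raw values that must be rounded first
  pred <- truth[, c("subject_id", "hemisphere", "c1", "c2", "c3", "c5")]
  set.seed(44)
  for (col in c("c1", "c2", "c3")) {
    pred[[col]] <- pred[[col]] + stats::runif(nrow(pred), -0.2, 0.2)
  }
  rep_perfect <- suppressWarnings(
    evaluate_run(truth, pred, n_boot = 20, seed = 1))
  m <- rep_perfect$metrics
  expect_true(all(m$point == 1))
  expect_true(all(vapply(rep_perfect$confusion,
                         function(cm) cm[["fp"]] + cm[["fn"]] == 0, logical(1))))
  # single cohort: pooled metrics equal the per-cohort metrics
  expect_setequal(unique(m$group), c("pooled", "toy"))
  pooled <- m[m$group == "pooled", c("hemisphere", "metric", "point")]
  bycoh <- m[m$group == "toy", c("hemisphere", "metric", "point")]
  expect_equal(pooled$point, bycoh$point)
  # shape: both hemispheres reported with one icc row plus one kappa per criterion
  expect_equal(sort(unique(m$hemisphere)), c("left", "right"))
  expect_lte(nrow(m), 2 * 2 * 5)

  noisy <- pred
  noisy$c1 <- round_prediction(pmin(pmax(truth$c1 + stats::rnorm(nrow(truth), 0, 0.7),
                                         0), 2), "C1")
  rep_noisy <- suppressWarnings(evaluate_run(truth, noisy, n_boot = 20, seed = 1))
  k1 <- rep_noisy$metrics
  k1 <- k1[k1$metric == "kappa_c1" & k1$group == "pooled", "point"]
  expect_true(all(k1 < 1))
})
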