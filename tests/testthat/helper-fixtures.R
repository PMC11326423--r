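# Shared lightweight fixtures. Heavier artifacts are memoized so several
# test files can reuse one computation.

tiny_grid <- c(10L, 8L, 8L)

tiny_net_args <- list(channels = c(2L, 2L, 3L, 3L, 4L), fc_widths = c(8L, 4L))

random_scores <- function(n, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    data.frame(
      c1 = sample(criterion_grid("C1"), n, replace = TRUE),
      c2 = sample(criterion_grid("C2"), n, replace = TRUE),
      c3 = sample(criterion_grid("C3"), n, replace = TRUE),
      c5 = sample(criterion_grid("C5"), n, replace = TRUE)
    )
  })
}

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small phantom cohort reused by several files.
small_cohort <- function() {
  memo("small_cohort", generate_cohort(
    cohort_spec("toy", 30, grid_shape = tiny_grid, noise_sd = 0.03,
                blur_fwhm = 0.8), seed = 42))
}
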