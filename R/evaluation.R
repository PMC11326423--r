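# Agreement statistics and method comparison.
#
# Composite scores are evaluated with intraclass correlation (default
# ICC(2,1): two-way random effects, single rater, absolute agreement --
# the variant appropriate to inter-rater reliability of single ratings);
# individual criteria with Cohen's kappa, quadratically weighted for the
# ordinal C1-C3 and unweighted for C5. Uncertainty comes from a subject-
# level bootstrap (100 replicates by default); two methods are compared by
# differencing the metric on the SAME bootstrap replicates and applying a
# Student's t-test to the replicate differences, with Bonferroni correction
# across the simultaneous tests.

#' Intraclass correlation between two paired rating vectors
#'
#' Computed from the two-way mean-square decomposition with n subjects and
#' k = 2 "raters" (e.g. manual vs predicted):
#' \itemize{
#'   \item `icc2_1` (default): `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)`,
#'     absolute agreement -- systematic offsets between the vectors count
#'     as disagreement;
#'   \item `icc3_1`: `(MSR - MSE) / (MSR + (k-1) MSE)`, consistency --
#'     offsets are forgiven.
#' }
#'
#' @param ratings_a,ratings_b Paired numeric vectors, length >= 5.
#' @param variant `"icc2_1"` (default) or `"icc3_1"`.
#' @return The ICC point estimate.
#' @export
icc <- function(ratings_a, ratings_b, variant = c("icc2_1", "icc3_1")) {
  variant <- match.arg(variant)
  if (length(ratings_a) != length(ratings_b)) stop_input("rating vectors must be paired")
  n <- length(ratings_a)
  if (n < 5) stop_input("ICC needs at least 5 paired ratings")
  if (any(!is.finite(ratings_a)) || any(!is.finite(ratings_b))) {
    stop_input("ratings must be finite")
  }
  m <- cbind(ratings_a, ratings_b)
  k <- 2L
  grand <- mean(m)
  sst <- sum((m - grand)^2)
  if (sst == 0) stop_input("ICC undefined: zero total variance")
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (variant == "icc2_1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Cohen's kappa for ordinal criterion ratings
#'
#' Chance-corrected agreement over a declared category grid:
#' `kappa = 1 - sum(w * O) / sum(w * E)` with observed proportions `O`,
#' chance expectation `E` from the marginal products, and disagreement
#' weights `w_ij = ((i - j)/(k - 1))^2` (quadratic) or `1_{i != j}`
#' (unweighted). The grid is declared, not inferred, so categories
#' unobserved in a sample still weight correctly; off-grid values are an
#' error -- round predictions with [round_prediction()] first.
#'
#' @param a,b Paired vectors with values in `categories`.
#' @param weighting `"quadratic"` or `"none"`.
#' @param categories Ordered category grid (e.g. [criterion_grid()]).
#' @return The kappa point estimate.
#' @export
cohen_kappa <- function(a, b, weighting = c("quadratic", "none"),
                        categories = criterion_grid("C1")) {
  weighting <- match.arg(weighting)
  if (length(a) != length(b)) stop_input("rating vectors must be paired")
  if (!all(a %in% categories) || !all(b %in% categories)) {
    stop_input("ratings contain values off the declared category grid; ",
               "round predictions onto the grid before computing kappa")
  }
  k <- length(categories)
  if (k < 2) stop_input("need at least 2 categories")
  O <- table(factor(a, levels = categories), factor(b, levels = categories)) / length(a)
  marg_a <- rowSums(O); marg_b <- colSums(O)
  E <- outer(marg_a, marg_b)
  idx <- seq_len(k)
  W <- if (weighting == "quadratic") {
    outer(idx, idx, function(i, j) ((i - j) / (k - 1))^2)
  } else {
    outer(idx, idx, function(i, j) as.numeric(i != j))
  }
  denom <- sum(W * E)
  if (denom == 0) stop_input("kappa undefined: both raters use a single identical category")
  1 - sum(W * O) / denom
}

#' Bootstrap a paired agreement metric
#'
#' Draws `n_boot` resamples of the subject indices with replacement,
#' recomputes `metric_fn(truth[idx], pred[idx])` on each, and summarizes:
#' bootstrap mean, SE (the sample SD of the replicates) and a 95%
#' percentile CI (normal approximation available as a switch). The
#' replicate index sets are retained so paired method comparisons can reuse
#' them.
#'
#' @param metric_fn Function of two paired vectors returning a scalar.
#' @param truth,predictions Paired vectors, length >= 2.
#' @param n_boot Number of replicates (default 100).
#' @param seed RNG seed.
#' @param ci_method `"percentile"` (default) or `"normal"`.
#' @param conf Confidence level (default 0.95).
#' @return A `metric_result` list: `point`, `boot_mean`, `boot_se`,
#'   `ci_lower`, `ci_upper`, `n`, `n_boot`, `seed`, `replicates`, `indices`.
#' @export
bootstrap_metric <- function(metric_fn, truth, predictions, n_boot = 100L,
                             seed = 1L, ci_method = c("percentile", "normal"),
                             conf = 0.95) {
  ci_method <- match.arg(ci_method)
  if (length(truth) != length(predictions)) stop_input("paired vectors required")
  n <- length(truth)
  if (n < 2) stop_input("need at least 2 paired observations")
  idx <- with_seed(seed,
                   matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n))
  reps <- apply(idx, 2L, function(ii) {
    tryCatch(metric_fn(truth[ii], predictions[ii]), error = function(e) NA_real_)
  })
  if (mean(is.na(reps)) > 0.5) {
    stop_input("metric undefined on more than half of the bootstrap replicates")
  }
  ok <- reps[!is.na(reps)]
  point <- metric_fn(truth, predictions)
  alpha <- 1 - conf
  ci <- if (ci_method == "percentile") {
    unname(stats::quantile(ok, c(alpha / 2, 1 - alpha / 2), type = 7))
  } else {
    mean(ok) + c(-1, 1) * stats::qnorm(1 - alpha / 2) * stats::sd(ok)
  }
  structure(list(point = point, boot_mean = mean(ok), boot_se = stats::sd(ok),
                 ci_lower = ci[1], ci_upper = ci[2], n = n,
                 n_boot = as.integer(n_boot), seed = seed,
                 replicates = reps, indices = idx, ci_method = ci_method),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("metric %.4f (bootstrap mean %.4f, SE %.4f, 95%% CI [%.4f, %.4f], n = %d, B = %d)\n",
              x$point, x$boot_mean, x$boot_se, x$ci_lower, x$ci_upper, x$n, x$n_boot))
  invisible(x)
}

#' Paired-bootstrap comparison of two prediction methods
#'
#' Both methods are evaluated on the SAME bootstrap resamples of the test
#' set; the per-replicate metric differences `d_b = metric_A(b) -
#' metric_B(b)` yield `t = mean(d) / sd(d)` (the denominator is the
#' bootstrap SE of the difference), a two-sided p-value from Student's t
#' with `n_boot - 1` degrees of freedom, and a Bonferroni-adjusted p-value
#' over `m_tests` simultaneous comparisons.
#'
#' @param truth Shared ground-truth vector.
#' @param preds_a,preds_b The two methods' predictions, aligned to `truth`.
#' @param metric_fn Paired metric, as in [bootstrap_metric()].
#' @param n_boot,seed Bootstrap controls (default 100 replicates).
#' @param m_tests Bonferroni family size (default 1).
#' @param labels Length-2 method labels.
#' @return A `comparison_result` list with the replicate differences, mean
#'   difference, SE, `t`, `p`, `p_adjusted` and `significant`
#'   (adjusted p < 0.05).
#' @export
compare_methods <- function(truth, preds_a, preds_b, metric_fn, n_boot = 100L,
                            seed = 1L, m_tests = 1L, labels = c("A", "B")) {
  if (length(preds_a) != length(truth) || length(preds_b) != length(truth)) {
    stop_input("prediction vectors must align with `truth`")
  }
  res_a <- bootstrap_metric(metric_fn, truth, preds_a, n_boot = n_boot, seed = seed)
  res_b <- bootstrap_metric(metric_fn, truth, preds_b, n_boot = n_boot, seed = seed)
  stopifnot(identical(res_a$indices, res_b$indices)) # paired-resample contract
  d <- res_a$replicates - res_b$replicates
  d <- d[!is.na(d)]
  mean_d <- mean(d)
  se_d <- stats::sd(d)
  t_stat <- if (se_d == 0) 0 else mean_d / se_d
  p <- if (se_d == 0 && mean_d == 0) 1 else 2 * stats::pt(-abs(t_stat), df = n_boot - 1)
  p_adj <- min(1, m_tests * p)
  structure(list(labels = labels, differences = d, mean_difference = mean_d,
                 se = se_d, t = t_stat, p = p, p_adjusted = p_adj,
                 m_tests = m_tests, significant = p_adj < 0.05,
                 n_boot = as.integer(n_boot), seed = seed,
                 metric_a = res_a, metric_b = res_b),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs %s: mean diff %.4f (SE %.4f), t = %.2f, p = %.4g, Bonferroni p = %.4g%s\n",
              x$labels[1], x$labels[2], x$mean_difference, x$se, x$t, x$p, x$p_adjusted,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Full agreement report for a prediction run
#'
#' Joins a truth table and a prediction table (rating-table dialect) on
#' subject and hemisphere, rounds predictions onto the criterion grids,
#' recomputes predicted composites from the rounded criteria, and reports
#' per hemisphere and per group (pooled plus each cohort): composite ICC,
#' quadratic kappas for C1-C3, unweighted kappa for C5 (all with bootstrap
#' CIs) and the IHI confusion counts at the composite >= 4 threshold.
#'
#' @param truth,predictions Rating data frames; `predictions` may carry raw
#'   (unrounded) criterion columns.
#' @param n_boot,seed Bootstrap controls.
#' @param icc_variant Passed to [icc()].
#' @return A `metric_report`: list with `metrics` (long data frame),
#'   `confusion` (per hemisphere x group) and `config`.
#' @export
evaluate_run <- function(truth, predictions, n_boot = 100L, seed = 1L,
                         icc_variant = "icc2_1") {
  key <- c("subject_id", "hemisphere")
  pred <- predictions
  for (cr in ihi_criteria()) {
    col <- tolower(cr)
    pred[[col]] <- round_prediction(pred[[col]], cr)
  }
  pred <- refresh_composites(pred)
  joined <- merge(truth, pred, by = key, suffixes = c("_true", "_pred"))
  if (!nrow(joined)) stop_input("truth and predictions share no subject/hemisphere rows")
  if (!"cohort_true" %in% names(joined)) {
    joined$cohort_true <- if ("cohort" %in% names(joined)) joined$cohort else "all"
  }

  metrics <- list(); confusion <- list()
  for (hemi in unique(joined$hemisphere)) {
    jh <- joined[joined$hemisphere == hemi, ]
    groups <- c(list(pooled = jh), split(jh, jh$cohort_true))
    for (gname in names(groups)) {
      g <- groups[[gname]]
      if (nrow(g) < 5) {
        warning("skipping group ", gname, " (", hemi, "): fewer than 5 subjects",
                call. = FALSE)
        next
      }
      add <- function(metric, mr) {
        metrics[[length(metrics) + 1]] <<- data.frame(
          hemisphere = hemi, group = gname, metric = metric,
          point = mr$point, boot_mean = mr$boot_mean, boot_se = mr$boot_se,
          ci_lower = mr$ci_lower, ci_upper = mr$ci_upper, n = mr$n,
          stringsAsFactors = FALSE)
      }
      seed_g <- derive_seed(seed, "eval", hemi, gname)
      add("icc_composite", bootstrap_metric(
        function(a, b) icc(a, b, variant = icc_variant),
        g$composite_true, g$composite_pred, n_boot = n_boot, seed = seed_g))
      for (cr in ihi_criteria()) {
        col <- tolower(cr)
        w <- if (cr == "C5") "none" else "quadratic"
        fn <- function(a, b) cohen_kappa(a, b, weighting = w,
                                         categories = criterion_grid(cr))
        mr <- tryCatch(
          bootstrap_metric(fn, g[[paste0(col, "_true")]], g[[paste0(col, "_pred")]],
                           n_boot = n_boot, seed = derive_seed(seed_g, cr)),
          error = function(e) {
            warning("kappa for ", cr, " in ", gname, " (", hemi, "): ",
                    conditionMessage(e), call. = FALSE)
            NULL
          })
        if (!is.null(mr)) add(paste0("kappa_", tolower(cr)), mr)
      }
      tt <- classify_ihi(g$composite_true); pp <- classify_ihi(g$composite_pred)
      confusion[[paste(hemi, gname, sep = ".")]] <- c(
        tp = sum(tt & pp), fp = sum(!tt & pp), fn = sum(tt & !pp), tn = sum(!tt & !pp))
    }
  }
  structure(list(metrics = do.call(rbind, metrics), confusion = confusion,
                 config = list(n_boot = as.integer(n_boot), seed = seed,
                               icc_variant = icc_variant,
                               threshold = ihi_threshold())),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("IHI agreement report (ICC variant ", x$config$icc_variant,
      ", B = ", x$config$n_boot, "):\n", sep = "")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
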