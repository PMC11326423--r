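# Stratified train/validation/test split search.
#
# 25% of each cohort is isolated as a test set; the remainder is split
# 80/20 into training and validation. To keep the held-out set
# representative, many random candidate partitions are drawn and the one
# minimizing distributional differences across the stratification variables
# (all IHI criteria plus age, weight, height, sex, handedness, centre) is
# retained. Numeric variables are compared with the two-sample
# Kolmogorov-Smirnov statistic, categorical ones with total-variation
# distance; the aggregate is the worst variable by default.

#' Split-search configuration
#'
#' @param test_fraction Fraction isolated as the test set (default 0.25).
#' @param val_fraction_of_remainder Fraction of the non-test subjects used
#'   for validation (default 0.20).
#' @param n_candidates Number of random candidate splits searched (default 200).
#' @param stratification_vars Variables balanced across sets.
#' @param aggregate `"max"` (worst variable, default) or `"mean"`.
#' @param seed Seed of the candidate stream.
#' @return A `split_config` object.
#' @export
split_config <- function(test_fraction = 0.25, val_fraction_of_remainder = 0.20,
                         n_candidates = 200L,
                         stratification_vars = c("c1", "c2", "c3", "c5", "age",
                                                 "weight", "height", "sex",
                                                 "handedness", "centre"),
                         aggregate = c("max", "mean"), seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1 ||
      val_fraction_of_remainder <= 0 || val_fraction_of_remainder >= 1) {
    stop_input("split fractions must lie in (0, 1)")
  }
  if (!is_count(n_candidates) || n_candidates < 1) stop_input("n_candidates must be >= 1")
  structure(list(test_fraction = test_fraction,
                 val_fraction_of_remainder = val_fraction_of_remainder,
                 n_candidates = as.integer(n_candidates),
                 stratification_vars = stratification_vars,
                 aggregate = match.arg(aggregate), seed = as.integer(seed)),
            class = "split_config")
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Sup-norm distance between the empirical CDFs of two samples, in `[0, 1]`.
#' Computed directly (ties are ubiquitous in ordinal rating data and only
#' the statistic, never the KS p-value, is used for split selection).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return The KS statistic.
#' @export
ks_statistic <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop_input("KS samples must be non-empty")
  if (any(!is.finite(sample_a)) || any(!is.finite(sample_b))) {
    stop_input("KS samples must be finite")
  }
  pts <- sort(unique(c(sample_a, sample_b)))
  Fa <- vapply(pts, function(t) mean(sample_a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(sample_b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Total-variation distance between category proportions of two samples.
tv_distance <- function(sample_a, sample_b) {
  lev <- union(unique(sample_a), unique(sample_b))
  pa <- table(factor(sample_a, levels = lev)) / length(sample_a)
  pb <- table(factor(sample_b, levels = lev)) / length(sample_b)
  sum(abs(pa - pb)) / 2
}

#' Train/validation/test set sizes
#'
#' `n_test = floor(test_fraction * n)`, `n_val = floor(val_fraction *
#' (n - n_test))`, `n_train` the remainder. With the default fractions this
#' reproduces e.g. (1205, 301, 502) at n = 2008, (596, 149, 248) at n = 993
#' and (240, 60, 100) at n = 400.
#'
#' @param n Number of subjects (>= 3).
#' @param cfg A [split_config()].
#' @return Named integer vector `c(n_train, n_val, n_test)`.
#' @export
split_sizes <- function(n, cfg = split_config()) {
  if (!is_count(n) || n < 3) stop_input("need at least 3 subjects to split")
  n_test <- as.integer(floor(cfg$test_fraction * n))
  n_val <- as.integer(floor(cfg$val_fraction_of_remainder * (n - n_test)))
  n_train <- as.integer(n - n_test - n_val)
  sizes <- c(n_train = n_train, n_val = n_val, n_test = n_test)
  if (any(sizes < 1)) {
    stop_input("n = ", n, " leaves an empty set under the configured fractions (",
               paste(names(sizes)[sizes < 1], collapse = ", "), ")")
  }
  sizes
}

#' One uniformly random candidate split
#'
#' Deterministic given `(cfg$seed, candidate_index)`.
#'
#' @param records Rating/covariate `data.frame` with a `subject_id` column
#'   (one row per subject).
#' @param cfg A [split_config()].
#' @param candidate_index Index of the candidate in the search stream.
#' @return A `split_assignment`: data frame (`subject_id`, `set`) plus
#'   metadata attributes.
#' @export
candidate_split <- function(records, cfg = split_config(), candidate_index = 1L) {
  if (!nrow(records)) stop_input("`records` is empty")
  check_strat_vars(records, cfg$stratification_vars)
  n <- nrow(records)
  sizes <- split_sizes(n, cfg)
  perm <- with_seed(derive_seed(cfg$seed, "candidate", candidate_index), sample.int(n))
  set <- character(n)
  set[perm[seq_len(sizes["n_test"])]] <- "test"
  set[perm[sizes["n_test"] + seq_len(sizes["n_val"])]] <- "validation"
  set[set == ""] <- "train"
  structure(data.frame(subject_id = records$subject_id, set = set,
                       stringsAsFactors = FALSE),
            sizes = sizes, candidate_index = candidate_index, seed = cfg$seed,
            class = c("split_assignment", "data.frame"))
}

check_strat_vars <- function(records, vars) {
  vars <- intersect(vars, names(records))
  for (v in vars) {
    if (anyNA(records[[v]])) {
      bad <- records$subject_id[which(is.na(records[[v]]))[1]]
      stop_input("missing value in stratification variable '", v,
                 "' (e.g. subject ", bad, ")")
    }
  }
  vars
}

#' Distributional discrepancy of a split
#'
#' Compares train+validation against test on every stratification variable:
#' KS statistic for numeric variables, total-variation distance for
#' categorical ones (both on a `[0, 1]` scale). Constant variables score 0
#' with a warning. The aggregate is the maximum (or mean) across variables.
#'
#' @param assignment A `split_assignment` covering `records`.
#' @param records The subject table the assignment was drawn from.
#' @param vars Stratification variables (defaults to those present).
#' @param aggregate `"max"` or `"mean"`.
#' @return List with `per_variable` (named numeric) and `aggregate` (scalar).
#' @export
split_badness <- function(assignment, records,
                          vars = c("c1", "c2", "c3", "c5", "age", "weight",
                                   "height", "sex", "handedness", "centre"),
                          aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  vars <- check_strat_vars(records, vars)
  idx <- match(records$subject_id, assignment$subject_id)
  if (anyNA(idx)) stop_input("assignment does not cover all records")
  set <- assignment$set[idx]
  in_test <- set == "test"
  per <- vapply(vars, function(v) {
    x <- records[[v]]
    if (length(unique(x)) < 2L) {
      warning("stratification variable '", v, "' is constant; discrepancy 0",
              call. = FALSE)
      return(0)
    }
    if (is.numeric(x)) ks_statistic(x[!in_test], x[in_test])
    else tv_distance(x[!in_test], x[in_test])
  }, numeric(1))
  list(per_variable = per,
       aggregate = if (aggregate == "max") max(per) else mean(per))
}

#' Search for the best-stratified split
#'
#' Draws `cfg$n_candidates` random splits and keeps the one with minimal
#' aggregate discrepancy (ties broken by lowest candidate index). The same
#' selector, applied to the non-test remainder, yields the train/validation
#' split.
#'
#' @param records Subject table (one row per subject).
#' @param cfg A [split_config()].
#' @param optimize_inner Also search the train-vs-validation assignment of
#'   the winning candidate with the same selection rule (default TRUE).
#' @return The winning `split_assignment`, with `badness` and
#'   `badness_candidates` attributes recording the search diagnostics.
#' @export
select_stratified_split <- function(records, cfg = split_config(),
                                    optimize_inner = TRUE) {
  vars <- check_strat_vars(records, cfg$stratification_vars)
  best <- NULL; best_bad <- Inf; all_bad <- numeric(cfg$n_candidates)
  for (i in seq_len(cfg$n_candidates)) {
    cand <- candidate_split(records, cfg, i)
    bad <- suppress_constant_warnings(
      split_badness(cand, records, vars, aggregate = cfg$aggregate))
    all_bad[i] <- bad$aggregate
    if (bad$aggregate < best_bad) {
      best <- cand
      best_bad <- bad$aggregate
      attr(best, "badness") <- bad
    }
  }
  attr(best, "badness_candidates") <- all_bad
  if (optimize_inner) best <- optimize_inner_split(best, records, cfg, vars)
  best
}

# The search loops call split_badness many times; a constant stratification
# variable would otherwise warn once per candidate.
suppress_constant_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("is constant; discrepancy 0", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Re-draws the train/validation labels of the non-test subjects, keeping the
# draw that minimizes train-vs-validation discrepancy under the same rule
# used for the outer split.
optimize_inner_split <- function(assignment, records, cfg, vars) {
  non_test <- assignment$subject_id[assignment$set != "test"]
  n_val <- sum(assignment$set == "validation")
  recs_nt <- records[records$subject_id %in% non_test, , drop = FALSE]
  best_val <- NULL; best_bad <- Inf
  for (i in seq_len(cfg$n_candidates)) {
    perm <- with_seed(derive_seed(cfg$seed, "inner", i), sample.int(length(non_test)))
    val_ids <- non_test[perm[seq_len(n_val)]]
    pseudo <- data.frame(subject_id = recs_nt$subject_id,
                         set = ifelse(recs_nt$subject_id %in% val_ids, "test", "train"),
                         stringsAsFactors = FALSE)
    bad <- suppress_constant_warnings(
      split_badness(pseudo, recs_nt, vars, aggregate = cfg$aggregate))
    if (bad$aggregate < best_bad) {
      best_bad <- bad$aggregate
      best_val <- val_ids
    }
  }
  assignment$set[assignment$set != "test"] <-
    ifelse(assignment$subject_id[assignment$set != "test"] %in% best_val,
           "validation", "train")
  attr(assignment, "inner_badness") <- best_bad
  assignment
}

#' Assemble a multi-cohort training strategy
#'
#' Pools the train and validation subsets of the named training cohorts;
#' every cohort's test subset is preserved untouched for evaluation, both
#' per cohort and pooled. The canonical strategies use one cohort, three
#' cohorts, or all cohorts as training sources.
#'
#' @param training_cohorts Character vector of cohort names to train on.
#' @param assignments Named list (by cohort) of `split_assignment`s.
#' @param records Named list (by cohort) of the matching subject tables.
#' @return List with `train`, `validation` (pooled data frames with a
#'   `cohort` column) and `test` (list: one data frame per cohort plus
#'   `$pooled`).
#' @export
assemble_strategy <- function(training_cohorts, assignments, records) {
  missing <- setdiff(training_cohorts, names(assignments))
  if (length(missing)) {
    stop_input("strategy names cohort(s) without a split: ", paste(missing, collapse = ", "))
  }
  pick <- function(cohort, which_set) {
    a <- assignments[[cohort]]
    r <- records[[cohort]]
    out <- r[r$subject_id %in% a$subject_id[a$set == which_set], , drop = FALSE]
    out$cohort <- cohort
    out
  }
  train <- do.call(rbind, lapply(training_cohorts, pick, which_set = "train"))
  val <- do.call(rbind, lapply(training_cohorts, pick, which_set = "validation"))
  test <- lapply(names(assignments), pick, which_set = "test")
  names(test) <- names(assignments)
  test$pooled <- do.call(rbind, test)
  # leakage guard: no test subject may appear in train or validation
  leaked <- intersect(test$pooled$subject_id, c(train$subject_id, val$subject_id))
  if (length(leaked)) stop("internal error: test subjects leaked into training: ",
                           paste(utils::head(leaked), collapse = ", "))
  list(train = train, validation = val, test = test,
       training_cohorts = training_cohorts)
}
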