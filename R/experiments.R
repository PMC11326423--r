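# End-to-end experiment orchestration at phantom scale.
#
# Reproduces the experimental design on synthetic data: generate several
# phantom cohorts with different acquisition characteristics, search
# stratified splits per cohort, train each architecture under each
# multi-cohort training strategy, predict on every held-out test set
# (per cohort and pooled) and evaluate. The default specification is a
# reduced-scale analogue of a four-cohort study (one large adolescent
# cohort, two mid-size cohorts, one older-adult cohort) sized to run on a
# single CPU; the same machinery scales to larger specs.

#' Default phantom cohorts of the reference experiment
#'
#' Four cohorts echoing the qualitative structure of the real multi-cohort
#' study at roughly one-tenth scale: different sizes, ages, raters,
#' left/right IHI prevalences and acquisition noise/blur/contrast.
#'
#' @param scale Multiplier on the cohort sizes (default 1).
#' @param grid_shape Crop extents used for every cohort.
#' @return Named list of [cohort_spec()]s.
#' @export
default_phantom_cohorts <- function(scale = 1, grid_shape = c(24L, 20L, 16L)) {
  specs <- list(
    cohort_spec("adolescent_eu", max(20, round(200 * scale)),
                target_prevalence_left = 0.21, target_prevalence_right = 0.08,
                noise_sd = 0.04, blur_fwhm = 1.2, intensity_scale = 1.00,
                age_mean = 14.5, age_sd = 1.3, rater_id = "R1",
                grid_shape = grid_shape),
    cohort_spec("twin_youngadult", max(20, round(100 * scale)),
                target_prevalence_left = 0.24, target_prevalence_right = 0.10,
                noise_sd = 0.06, blur_fwhm = 1.8, intensity_scale = 0.90,
                age_mean = 22.9, age_sd = 2.8, rater_id = "R2",
                grid_shape = grid_shape),
    cohort_spec("twin_child", max(20, round(40 * scale)),
                target_prevalence_left = 0.27, target_prevalence_right = 0.17,
                noise_sd = 0.05, blur_fwhm = 1.0, intensity_scale = 1.05,
                age_mean = 11.3, age_sd = 1.3, rater_id = "R2",
                grid_shape = grid_shape),
    cohort_spec("older_adult", max(20, round(100 * scale)),
                target_prevalence_left = 0.21, target_prevalence_right = 0.06,
                noise_sd = 0.05, blur_fwhm = 1.5, intensity_scale = 0.95,
                age_mean = 63.5, age_sd = 7.6, rater_id = "R2",
                grid_shape = grid_shape))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Specification of a full phantom experiment
#'
#' @param cohorts Named list of [cohort_spec()]s.
#' @param strategies Named list mapping strategy labels to the cohort names
#'   trained on. The default mirrors the three canonical strategies:
#'   first cohort only; first three; all.
#' @param architectures Subset of `c("conv5fc3", "resnet3d", "secnn", "ridge")`.
#' @param criteria IHI criteria to model.
#' @param hemispheres `"left"`, `"right"` or both.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for artifacts.
#' @param net_args List of builder arguments shared by the deep families
#'   (channel widths etc.); the default is a reduced-width preset.
#' @param train Training configuration ([train_config()]).
#' @param split A [split_config()].
#' @param n_boot Bootstrap replicates in the evaluation reports.
#' @param mirror_right Map right-hemisphere crops into the left frame before
#'   training/prediction (default TRUE).
#' @return An `experiment_spec` object.
#' @export
experiment_spec <- function(cohorts = default_phantom_cohorts(),
                            strategies = NULL,
                            architectures = "conv5fc3",
                            criteria = ihi_criteria(),
                            hemispheres = "left",
                            seed = 1L, out_dir = tempfile("ihi_experiment_"),
                            net_args = list(channels = c(4L, 8L, 16L, 16L, 32L),
                                            fc_widths = c(64L, 16L)),
                            train = train_config(learning_rate = 1e-3, max_epochs = 20L),
                            split = split_config(n_candidates = 50L),
                            n_boot = 100L, mirror_right = TRUE) {
  if (is.null(names(cohorts))) {
    names(cohorts) <- vapply(cohorts, `[[`, character(1), "name")
  }
  if (is.null(strategies)) {
    nm <- names(cohorts)
    strategies <- list(first = nm[1],
                       multi = nm[seq_len(min(3, length(nm)))],
                       all = nm)
  }
  bad <- setdiff(unlist(strategies), names(cohorts))
  if (length(bad)) stop_input("strategy references unknown cohort(s): ",
                              paste(bad, collapse = ", "))
  stopifnot(all(architectures %in% c("conv5fc3", "resnet3d", "secnn", "ridge")),
            all(criteria %in% ihi_criteria()),
            all(hemispheres %in% c("left", "right")))
  structure(list(cohorts = cohorts, strategies = strategies,
                 architectures = architectures, criteria = criteria,
                 hemispheres = hemispheres, seed = as.integer(seed),
                 out_dir = out_dir, net_args = net_args, train = train,
                 split = split, n_boot = as.integer(n_boot),
                 mirror_right = isTRUE(mirror_right)),
            class = "experiment_spec")
}

# Crops of one hemisphere in the canonical (left) training frame.
hemisphere_crops <- function(cohort, hemisphere, mirror_right = TRUE) {
  crops <- cohort$crops[[hemisphere]]
  if (hemisphere == "right" && mirror_right) crops <- lapply(crops, mirror_hemisphere)
  names(crops) <- vapply(crops, attr, character(1), "subject_id")
  crops
}

# Label vector (raw observed criterion scores) aligned to subject ids.
hemisphere_labels <- function(cohort, hemisphere, criterion, subject_ids) {
  df <- cohort$ratings_observed
  df <- df[df$hemisphere == hemisphere, ]
  df[[tolower(criterion)]][match(subject_ids, df$subject_id)]
}

train_one_model <- function(arch, criterion, hemisphere, sets, spec, seed) {
  x_train <- sets$crops[sets$train_ids]
  x_val <- sets$crops[sets$val_ids]
  y_train <- sets$labels[[criterion]][sets$train_ids]
  y_val <- sets$labels[[criterion]][sets$val_ids]
  if (arch == "ridge") {
    fit <- ridge_nested_cv(crops_to_matrix(c(x_train, x_val)),
                           c(y_train, y_val), seed = seed)
    fit$criterion <- criterion; fit$hemisphere <- hemisphere
    fit
  } else {
    dims <- dim(x_train[[1]])
    net <- do.call(build_network,
                   c(list(family = arch, input_dims = dims), spec$net_args,
                     list(seed = seed)))
    cfg <- spec$train
    cfg$seed <- seed
    train_regressor(net, x_train, y_train, x_val, y_val, cfg,
                    criterion = criterion, hemisphere = hemisphere)
  }
}

#' Run a phantom experiment end to end
#'
#' Stages: generate cohorts, stratified split search per cohort, strategy
#' assembly (with a leakage assertion), model training per
#' strategy x architecture x criterion x hemisphere, prediction on every
#' test set, and agreement reports per hemisphere and cohort. All artifacts
#' (rating tables, assignments, prediction tables, reports, checkpoints and
#' a manifest) are written under `spec$out_dir`; every stage seed derives
#' deterministically from the master seed, so a rerun reproduces the run.
#'
#' @param spec An [experiment_spec()].
#' @return Invisibly, a list with `manifest`, `reports` (per strategy x
#'   architecture x hemisphere `metric_report`s), `predictions` and
#'   `models`.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = spec$seed, stages = list(), artifacts = character())

  log_stage <- function(name, note = "") {
    manifest$stages[[name]] <<- list(completed = TRUE, note = note)
    message("[ihiscore] stage ", name, if (nzchar(note)) paste0(": ", note) else "")
  }

  cohorts <- lapply(spec$cohorts, function(cs) {
    generate_cohort(cs, seed = derive_seed(spec$seed, "data", cs$name))
  })
  log_stage("generate", paste(length(cohorts), "cohorts"))

  subject_tables <- lapply(cohorts, function(co) {
    co$ratings_observed[co$ratings_observed$hemisphere == "left", ]
  })
  assignments <- lapply(names(cohorts), function(nm) {
    cfg <- spec$split
    cfg$seed <- derive_seed(spec$seed, "split", nm)
    a <- select_stratified_split(subject_tables[[nm]], cfg)
    utils::write.table(a, file.path(spec$out_dir, paste0("split_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    a
  })
  names(assignments) <- names(cohorts)
  log_stage("split")

  models <- list(); predictions <- list(); reports <- list()
  for (st_name in names(spec$strategies)) {
    strat <- assemble_strategy(spec$strategies[[st_name]], assignments, subject_tables)
    for (hemi in spec$hemispheres) {
      # crops and labels across all cohorts, in the canonical frame
      crops <- list(); labels <- stats::setNames(vector("list", length(spec$criteria)),
                                                 spec$criteria)
      for (nm in names(cohorts)) {
        cc <- hemisphere_crops(cohorts[[nm]], hemi, spec$mirror_right)
        crops <- c(crops, cc)
        for (cr in spec$criteria) {
          lab <- hemisphere_labels(cohorts[[nm]], hemi, cr, names(cc))
          labels[[cr]] <- c(labels[[cr]], stats::setNames(lab, names(cc)))
        }
      }
      sets <- list(crops = crops, labels = labels,
                   train_ids = strat$train$subject_id,
                   val_ids = strat$validation$subject_id)
      for (arch in spec$architectures) {
        key <- paste(st_name, arch, hemi, sep = ".")
        fits <- lapply(spec$criteria, function(cr) {
          train_one_model(arch, cr, hemi, sets, spec,
                          seed = derive_seed(spec$seed, "train", st_name, arch, cr, hemi))
        })
        names(fits) <- spec$criteria
        models[[key]] <- fits
        saveRDS(fits, file.path(spec$out_dir, paste0("model_", key, ".rds")))

        test_ids <- strat$test$pooled$subject_id
        pred <- data.frame(subject_id = test_ids, hemisphere = hemi,
                           stringsAsFactors = FALSE)
        for (cr in spec$criteria) {
          pred[[tolower(cr)]] <- predict_criterion(fits[[cr]], crops[test_ids])
        }
        predictions[[key]] <- pred
        write_ratings(pred, file.path(spec$out_dir, paste0("pred_", key, ".tsv")))

        truth <- do.call(rbind, lapply(cohorts, function(co) {
          co$ratings_observed[co$ratings_observed$hemisphere == hemi &
                                co$ratings_observed$subject_id %in% test_ids, ]
        }))
        full_pred <- pred
        for (cr in setdiff(ihi_criteria(), spec$criteria)) {
          full_pred[[tolower(cr)]] <- truth[[tolower(cr)]][
            match(paste(full_pred$subject_id, full_pred$hemisphere),
                  paste(truth$subject_id, truth$hemisphere))]
        }
        rep <- evaluate_run(truth, full_pred, n_boot = spec$n_boot,
                            seed = derive_seed(spec$seed, "eval", key))
        reports[[key]] <- rep
        jsonlite::write_json(
          list(metrics = rep$metrics, confusion = rep$confusion, config = rep$config),
          file.path(spec$out_dir, paste0("report_", key, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
    }
  }
  log_stage("train_predict_evaluate",
            paste(length(models), "model sets"))

  manifest$artifacts <- list.files(spec$out_dir)
  manifest$n_models <- length(models)
  manifest$combinations <- length(spec$strategies) * length(spec$architectures) *
    length(spec$criteria) * length(spec$hemispheres)
  jsonlite::write_json(manifest, file.path(spec$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, reports = reports,
                 predictions = predictions, models = models,
                 assignments = assignments, cohorts = cohorts))
}
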