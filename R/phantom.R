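# Synthetic hippocampus phantom.
#
# Generates grey-matter-like 3D crops whose geometry varies monotonically
# with four latent scores matching the IHI criteria, plus multi-cohort
# structure (noise, blur, contrast, prevalence, rater noise) so the whole
# rating pipeline can be exercised and tested without restricted imaging
# data. The geometry is deliberately simple -- an ellipsoidal "hippocampal
# body" plus wedge-shaped grooves -- the point is a monotone, learnable
# latent-to-image map, not anatomical realism:
#   t1: in-plane rotation of the body from horizontal (0) to vertical (1),
#       with the short axis fattening (roundness) as t1 grows;
#   t2: depth of a dark collateral-sulcus wedge rising from below;
#   t3: medial translation of the body;
#   t5: depth of a secondary fusiform-sulcus groove on the medial side.
# Latent 0 maps to criterion score 0 and latent 1 to score 2.

#' Phantom latent scores
#'
#' @param t1,t2,t3,t5 Latents in `[0, 1]` driving, respectively, body
#'   verticality/roundness, collateral-sulcus depth, medial position and
#'   fusiform-sulcus depth.
#' @return Named numeric vector of class `phantom_latents`.
#' @export
phantom_latents <- function(t1 = 0, t2 = 0, t3 = 0, t5 = 0) {
  lat <- c(t1 = t1, t2 = t2, t3 = t3, t5 = t5)
  if (any(!is.finite(lat)) || any(lat < 0 | lat > 1)) {
    stop_input("phantom latents must lie in [0, 1]")
  }
  structure(lat, class = c("phantom_latents", "numeric"))
}

# Fractional coordinate grids (voxel centres), recycled across components.
frac_grids <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  list(
    ux = array(rep((seq_len(nx) - 0.5) / nx, times = ny * nz), dim = grid_shape),
    uy = array(rep(rep((seq_len(ny) - 0.5) / ny, each = nx), times = nz), dim = grid_shape),
    uz = array(rep((seq_len(nz) - 0.5) / nz, each = nx * ny), dim = grid_shape)
  )
}

# Default per-subject anatomy of the phantom; `anatomy` arguments override
# entries to model inter-subject variability beyond the criterion latents.
default_anatomy <- function() {
  list(size = 1,        # overall scale of the hippocampal body
       body_amp = 0.85, # grey-matter probability of the body core
       elong = 1,       # anterior-posterior elongation of the body
       plate_amp = 0.40, plate_z = 0.28, plate_w = 0.08, # parahippocampal plate
       roundness_gain = 1) # t1 -> short-axis fattening; 0 isolates pure rotation
}

# Noiseless phantom geometry on [0,1] intensities. `offset` translates the
# whole anatomy (fractional units), emulating residual misregistration left
# over after spatial normalization.
phantom_geometry <- function(latents, grid_shape, offset = c(0, 0, 0),
                             anatomy = list()) {
  an <- utils::modifyList(default_anatomy(), anatomy)
  g <- frac_grids(grid_shape)
  g$ux <- g$ux - offset[1]; g$uy <- g$uy - offset[2]; g$uz <- g$uz - offset[3]
  t1 <- latents[["t1"]]; t2 <- latents[["t2"]]
  t3 <- latents[["t3"]]; t5 <- latents[["t5"]]

  # cortical background: low base plus a parahippocampal plate
  img <- 0.15 + an$plate_amp * exp(-((g$uz - an$plate_z) / an$plate_w)^2)

  # hippocampal body: ellipsoid rotated in the coronal (x,z) plane by t1*90deg,
  # translated medially (+x) by t3, short axis fattened with t1 (roundness)
  theta <- t1 * pi / 2
  cx <- 0.30 + 0.22 * t3; cz <- 0.56; cy <- 0.50
  dx <- g$ux - cx; dz <- g$uz - cz
  p1 <- dx * cos(theta) + dz * sin(theta)
  p2 <- -dx * sin(theta) + dz * cos(theta)
  p3 <- g$uy - cy
  a <- 0.16 * an$size
  cc <- (0.07 + 0.05 * t1 * an$roundness_gain) * an$size
  b <- 0.30 * an$size * an$elong
  q <- (p1 / a)^2 + (p2 / cc)^2 + (p3 / b)^2
  img <- img + an$body_amp * stats::plogis((1 - q) / 0.15)

  # collateral-sulcus wedge: dark groove rising from below at the lateral side
  img <- img - 0.80 * t2 * wedge_weight(g, x_pos = 0.30, top = 0.18 + 0.32 * t2)
  # fusiform-sulci groove on the medial side
  img <- img - 0.70 * t5 * wedge_weight(g, x_pos = 0.64, top = 0.14 + 0.26 * t5)

  pmin(pmax(img, 0), 1)
}

# Soft wedge mask: full weight below `top`, fading over ~3% of the box,
# laterally localized around x_pos and widening toward the bottom.
wedge_weight <- function(g, x_pos, top) {
  halfw <- 0.035 + 0.030 * (1 - g$uz)
  stats::plogis((top - g$uz) / 0.03) * exp(-((g$ux - x_pos) / halfw)^2)
}

# Separable Gaussian smoothing; fwhm in voxels.
gauss_smooth3d <- function(arr, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    n <- dim(arr)[axis]
    if (n < 2) next
    K <- outer(seq_len(n), seq_len(n), function(i, j) stats::dnorm(i - j, sd = sigma))
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(arr, perm)
    d <- dim(ap)
    m <- K %*% matrix(ap, nrow = n)
    arr <- aperm(array(m, d), order(perm))
  }
  arr
}

#' Render one phantom grey-matter crop
#'
#' Deterministic given `(latents, seed)`: the geometry is a pure function of
#' the latents; blur, intensity scaling and voxel noise emulate cohort-level
#' acquisition differences.
#'
#' @param latents A [phantom_latents()] vector.
#' @param grid_shape Integer length-3 crop extents (default `c(72, 53, 33)`,
#'   matching the default ROI).
#' @param seed Seed for the voxel noise (ignored when `noise_sd = 0`).
#' @param noise_sd Additive Gaussian noise SD in grey-matter-probability units.
#' @param blur_fwhm Gaussian blur FWHM in voxels.
#' @param intensity_scale Multiplicative contrast factor applied to the
#'   geometry before noise.
#' @param offset Length-3 fractional translation of the whole anatomy,
#'   emulating residual misregistration after spatial normalization.
#' @param anatomy Named list overriding per-subject anatomy (body `size`,
#'   `body_amp`, `elong`, parahippocampal `plate_amp`/`plate_z`/`plate_w`,
#'   `roundness_gain`), modelling inter-subject variability beyond the
#'   criterion latents.
#' @param hemisphere,subject_id,cohort Metadata forwarded to [gm_crop()].
#' @return A `gm_crop` with values in `[0, 1]`.
#' @export
render_crop <- function(latents, grid_shape = c(72L, 53L, 33L), seed = NULL,
                        noise_sd = 0, blur_fwhm = 0, intensity_scale = 1,
                        offset = c(0, 0, 0), anatomy = list(),
                        hemisphere = "left", subject_id = NA_character_,
                        cohort = NA_character_) {
  if (!inherits(latents, "phantom_latents")) latents <- do.call(phantom_latents, as.list(latents))
  if (length(grid_shape) != 3L || any(grid_shape < 8)) {
    stop_input("grid_shape must be 3 extents, each >= 8, to contain the phantom geometry")
  }
  img <- phantom_geometry(latents, grid_shape, offset = offset, anatomy = anatomy)
  if (blur_fwhm > 0) img <- gauss_smooth3d(img, blur_fwhm)
  img <- img * intensity_scale
  if (noise_sd > 0) {
    img <- img + with_seed(seed, array(stats::rnorm(prod(grid_shape), sd = noise_sd),
                                       dim = grid_shape))
  }
  gm_crop(pmin(pmax(img, 0), 1), hemisphere = hemisphere,
          subject_id = subject_id, cohort = cohort)
}

#' Mask of the voxels the phantom geometry can touch
#'
#' Union of the voxels whose noiseless intensity varies across the 16 corner
#' configurations of the latent hypercube. Used as ground truth when checking
#' that model saliency concentrates on the generative anatomy.
#'
#' @param grid_shape Crop extents.
#' @return Logical 3D array.
#' @export
phantom_geometry_mask <- function(grid_shape = c(72L, 53L, 33L)) {
  corners <- expand.grid(t1 = c(0, 1), t2 = c(0, 1), t3 = c(0, 1), t5 = c(0, 1))
  stack <- vapply(seq_len(nrow(corners)),
                  function(i) as.vector(phantom_geometry(unlist(corners[i, ]), grid_shape)),
                  numeric(prod(grid_shape)))
  rng <- apply(stack, 1L, function(v) max(v) - min(v))
  array(rng > 1e-4, dim = grid_shape)
}

# Support of the collateral-sulcus wedge at full depth (internal; used by
# the monotone-signal tests).
sulcus_wedge_mask <- function(grid_shape, component = c("collateral", "fusiform")) {
  component <- match.arg(component)
  g <- frac_grids(grid_shape)
  w <- if (component == "collateral") wedge_weight(g, 0.30, 0.18 + 0.32) else
    wedge_weight(g, 0.64, 0.14 + 0.26)
  w > 0.3
}

#' Map phantom latents to ground-truth criterion scores
#'
#' `score = round_prediction(2 * latent, criterion)`: monotone in each
#' latent, 0 at latent 0 and 2 at latent 1.
#'
#' @param latents A [phantom_latents()] vector.
#' @return Named numeric vector with entries `C1, C2, C3, C5` on their grids.
#' @export
latents_to_scores <- function(latents) {
  if (!inherits(latents, "phantom_latents")) latents <- do.call(phantom_latents, as.list(latents))
  c(C1 = round_prediction(2 * latents[["t1"]], "C1"),
    C2 = round_prediction(2 * latents[["t2"]], "C2"),
    C3 = round_prediction(2 * latents[["t3"]], "C3"),
    C5 = round_prediction(2 * latents[["t5"]], "C5"))
}

#' Simulate rater label noise
#'
#' Each criterion is independently perturbed one grid step up or down with
#' probability `flip_prob` (direction uniform; at the ends of the scale the
#' only admissible direction is taken), emulating inter/intra-rater
#' disagreement. The default `flip_prob` used by [cohort_spec()] is
#' calibrated so that truth-vs-observed composite ICC over 500 subjects
#' falls in the 0.70-0.85 band typical of expert inter-rater reliability.
#'
#' @param scores Named numeric vector (`C1, C2, C3, C5`) on the rating grids.
#' @param flip_prob Per-criterion perturbation probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return Perturbed named score vector, still on the grids.
#' @export
simulate_rater <- function(scores, flip_prob, seed = NULL) {
  scores <- check_scores(scores)
  if (!is.numeric(flip_prob) || flip_prob < 0 || flip_prob > 1) {
    stop_input("flip_prob must lie in [0, 1]")
  }
  with_seed(seed, {
    out <- scores
    for (cr in ihi_criteria()) {
      if (stats::runif(1) < flip_prob) {
        step <- criterion_step(cr) * sample(c(-1, 1), 1L)
        cand <- scores[[cr]] + step
        if (cand < 0 || cand > 2) cand <- scores[[cr]] - step
        out[[cr]] <- cand
      }
    }
    out
  })
}

# ---- cohort-level generation ------------------------------------------------

#' Specification of one phantom cohort
#'
#' Defaults mirror the population structure reported for real cohorts:
#' left-hemisphere IHI prevalence about 20%, right about 8%, one rater per
#' cohort, cohort-specific acquisition noise/blur/contrast and age structure.
#'
#' @param name Cohort identifier.
#' @param n_subjects Number of subjects.
#' @param target_prevalence_left,target_prevalence_right Expected fraction of
#'   hemispheres with composite >= 4.
#' @param noise_sd,blur_fwhm,intensity_scale Acquisition model per
#'   [render_crop()].
#' @param age_mean,age_sd Age distribution (years).
#' @param rater_id Label of the cohort's rater.
#' @param rater_flip_prob Rater noise per [simulate_rater()]. The default
#'   0.65 calibrates truth-vs-observed composite ICC into the 0.70-0.85
#'   inter-rater band at n = 500.
#' @param position_jitter_sd SD (fractional units) of the per-subject
#'   translation of the anatomy, emulating residual misregistration after
#'   spatial normalization (default 0.03, roughly one voxel).
#' @param anatomy_variability Multiplier on the per-subject anatomical
#'   nuisance variation (body size/amplitude/elongation, plate thickness and
#'   position); 1 is the realistic default, 0 makes all subjects share one
#'   anatomy apart from the criterion latents.
#' @param grid_shape Crop extents.
#' @param n_centres Number of imaging centres to simulate.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(name, n_subjects,
                        target_prevalence_left = 0.20,
                        target_prevalence_right = 0.08,
                        noise_sd = 0.05, blur_fwhm = 1.5, intensity_scale = 1,
                        age_mean = 20, age_sd = 3,
                        rater_id = "R1", rater_flip_prob = 0.65,
                        position_jitter_sd = 0.03, anatomy_variability = 1,
                        grid_shape = c(72L, 53L, 33L), n_centres = 2L) {
  if (!is_count(n_subjects) || n_subjects < 1) stop_input("n_subjects must be >= 1")
  for (p in c(target_prevalence_left, target_prevalence_right)) {
    if (!is.finite(p) || p < 0 || p > 1) stop_input("target prevalences must lie in [0, 1]")
  }
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 target_prevalence_left = target_prevalence_left,
                 target_prevalence_right = target_prevalence_right,
                 noise_sd = noise_sd, blur_fwhm = blur_fwhm,
                 intensity_scale = intensity_scale,
                 age_mean = age_mean, age_sd = age_sd,
                 rater_id = rater_id, rater_flip_prob = rater_flip_prob,
                 position_jitter_sd = position_jitter_sd,
                 anatomy_variability = anatomy_variability,
                 grid_shape = as.integer(grid_shape), n_centres = as.integer(n_centres)),
            class = "cohort_spec")
}

# Beta parameters of the bimodal latent prior: "typical" anatomy near 0,
# "IHI" anatomy near 1.
LATENT_BETA_TYPICAL <- c(1.3, 6.5)
LATENT_BETA_IHI <- c(6.5, 1.6)

# Exact pmf of one criterion score when 2*latent ~ rounded Beta draw.
criterion_score_pmf <- function(criterion, shape) {
  grid <- criterion_grid(criterion)
  step <- criterion_step(criterion)
  lo <- pmax((grid - step / 2) / 2, 0)
  hi <- pmin((grid + step / 2) / 2, 1)
  p <- stats::pbeta(hi, shape[1], shape[2]) - stats::pbeta(lo, shape[1], shape[2])
  names(p) <- grid
  p / sum(p)
}

# Exact P(composite >= 4) under a given latent Beta, by convolving the four
# per-criterion score pmfs on the 0.5 grid.
prob_ihi_given_beta <- function(shape) {
  pmf <- rep(0, 17) # composite support 0, 0.5, ..., 8
  pmf[1] <- 1
  for (cr in ihi_criteria()) {
    p <- criterion_score_pmf(cr, shape)
    idx <- as.numeric(names(p)) / 0.5
    new <- rep(0, 17)
    for (j in seq_along(p)) {
      if (p[j] > 0) {
        shifted <- c(rep(0, idx[j]), pmf)[1:17]
        new <- new + p[j] * shifted
      }
    }
    pmf <- new
  }
  sum(pmf[(4 / 0.5 + 1):17])
}

# Mixture weight on the IHI mode needed to hit a target prevalence.
solve_mixture_weight <- function(target) {
  p0 <- prob_ihi_given_beta(LATENT_BETA_TYPICAL)
  p1 <- prob_ihi_given_beta(LATENT_BETA_IHI)
  w <- (target - p0) / (p1 - p0)
  if (w < 0 || w > 1) {
    stop_input("target prevalence ", target, " unattainable with the latent prior ",
               "(reachable range [", signif(p0, 3), ", ", signif(p1, 3), "])")
  }
  w
}

draw_latents <- function(n, prevalence) {
  w <- solve_mixture_weight(prevalence)
  z <- stats::runif(n) < w
  t(vapply(z, function(ihi) {
    sh <- if (ihi) LATENT_BETA_IHI else LATENT_BETA_TYPICAL
    stats::rbeta(4, sh[1], sh[2])
  }, numeric(4)))
}

#' Generate a phantom cohort
#'
#' Draws per-hemisphere latents from a bimodal typical-vs-IHI Beta mixture
#' whose weight is solved exactly so the expected fraction of hemispheres
#' with composite >= 4 matches the target prevalence, renders the crops with
#' the cohort's acquisition model, applies rater noise, and attaches
#' covariates. Fully reproducible given `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master seed for the cohort.
#' @return A `phantom_cohort`: list with elements `spec`, `ratings_truth`,
#'   `ratings_observed` (rating-table data frames, both hemispheres),
#'   `crops` (`$left`, `$right`: lists of `gm_crop`) and `latents`.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  ids <- sprintf("%s_%04d", spec$name, seq_len(n))

  with_seed(derive_seed(seed, "cohort", spec$name), {
    lat <- list(left = draw_latents(n, spec$target_prevalence_left),
                right = draw_latents(n, spec$target_prevalence_right))
    off <- list(left = matrix(stats::rnorm(3 * n, 0, spec$position_jitter_sd), n, 3),
                right = matrix(stats::rnorm(3 * n, 0, spec$position_jitter_sd), n, 3))
    av <- spec$anatomy_variability
    draw_anatomy <- function() {
      lapply(seq_len(n), function(i) {
        list(size = stats::rnorm(1, 1, 0.06 * av),
             body_amp = stats::rnorm(1, 0.85, 0.05 * av),
             elong = stats::rnorm(1, 1, 0.08 * av),
             plate_amp = stats::rnorm(1, 0.40, 0.05 * av),
             plate_z = stats::rnorm(1, 0.28, 0.02 * av))
      })
    }
    anat <- list(left = draw_anatomy(), right = draw_anatomy())
    sex <- sample(c("M", "F"), n, replace = TRUE)
    height <- round(ifelse(sex == "M", stats::rnorm(n, 176, 7), stats::rnorm(n, 163, 6)), 1)
    covar <- data.frame(
      subject_id = ids,
      age = round(stats::rnorm(n, spec$age_mean, spec$age_sd), 1),
      sex = sex,
      height = height,
      weight = round(0.9 * (height - 100) + stats::rnorm(n, 0, 8), 1),
      handedness = sample(c("R", "L"), n, replace = TRUE, prob = c(0.9, 0.1)),
      centre = sample(sprintf("%s_c%d", spec$name, seq_len(spec$n_centres)), n, replace = TRUE),
      cohort = spec$name,
      stringsAsFactors = FALSE
    )
  })

  make_table <- function(hemi, observed) {
    rows <- lapply(seq_len(n), function(i) {
      truth <- latents_to_scores(phantom_latents(
        t1 = lat[[hemi]][i, 1], t2 = lat[[hemi]][i, 2],
        t3 = lat[[hemi]][i, 3], t5 = lat[[hemi]][i, 4]))
      sc <- if (observed) {
        simulate_rater(truth, spec$rater_flip_prob,
                       seed = derive_seed(seed, "rater", spec$name, hemi, i))
      } else truth
      data.frame(subject_id = ids[i], hemisphere = hemi,
                 c1 = sc[["C1"]], c2 = sc[["C2"]], c3 = sc[["C3"]], c5 = sc[["C5"]],
                 rater_id = spec$rater_id, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- refresh_composites(df)
    merge(df, covar, by = "subject_id", sort = FALSE)[, RATING_COLUMNS]
  }

  truth_df <- rbind(make_table("left", FALSE), make_table("right", FALSE))
  obs_df <- rbind(make_table("left", TRUE), make_table("right", TRUE))

  crops <- lapply(c(left = "left", right = "right"), function(hemi) {
    lapply(seq_len(n), function(i) {
      render_crop(phantom_latents(t1 = lat[[hemi]][i, 1], t2 = lat[[hemi]][i, 2],
                                  t3 = lat[[hemi]][i, 3], t5 = lat[[hemi]][i, 4]),
                  grid_shape = spec$grid_shape,
                  seed = derive_seed(seed, "crop", spec$name, hemi, i),
                  noise_sd = spec$noise_sd, blur_fwhm = spec$blur_fwhm,
                  intensity_scale = spec$intensity_scale,
                  offset = off[[hemi]][i, ], anatomy = anat[[hemi]][[i]],
                  hemisphere = hemi, subject_id = ids[i], cohort = spec$name)
    })
  })

  structure(list(spec = spec, seed = seed,
                 ratings_truth = truth_df, ratings_observed = obs_df,
                 crops = crops,
                 latents = lat),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  prev <- tapply(x$ratings_truth$ihi_flag, x$ratings_truth$hemisphere, mean)
  cat(sprintf("phantom cohort '%s': %d subjects, grid %s, IHI prevalence L %.1f%% / R %.1f%%\n",
              x$spec$name, x$spec$n_subjects, paste(x$spec$grid_shape, collapse = "x"),
              100 * prev[["left"]], 100 * prev[["right"]]))
  invisible(x)
}

#' Angle-driven nonlinear phantom benchmark
#'
#' A phantom variant in which the only varying criterion latent is the
#' hippocampal-body verticality `t1`, with the roundness confound disabled
#' (`roundness_gain = 0`) so the criterion score depends on the body's
#' in-plane angle rather than on any mean-intensity cue, and with realistic
#' per-subject anatomy nuisance and residual misregistration. This is the
#' benchmark on which configural (shape) readout is required: fixed-voxel
#' linear models degrade here while convolutional models remain accurate.
#'
#' @param n Number of subjects.
#' @param seed Master seed.
#' @param grid_shape Crop extents.
#' @param position_jitter_sd Residual-misregistration SD (fractional units).
#' @param noise_sd,blur_fwhm Acquisition model per [render_crop()].
#' @return List with `crops` (list of `gm_crop`), `scores` (on-grid C1
#'   ground truth) and `latents` (the underlying `t1` values).
#' @export
angle_phantom_dataset <- function(n, seed = 1L, grid_shape = c(24L, 20L, 16L),
                                  position_jitter_sd = 0.06,
                                  noise_sd = 0.02, blur_fwhm = 1.0) {
  with_seed(derive_seed(seed, "angle_phantom"), {
    t1 <- stats::rbeta(n, 0.8, 0.8)
    offs <- matrix(stats::rnorm(3 * n, 0, position_jitter_sd), n, 3)
    anat <- lapply(seq_len(n), function(i) {
      list(size = stats::rnorm(1, 1, 0.06),
           body_amp = stats::rnorm(1, 0.85, 0.05),
           elong = stats::rnorm(1, 1, 0.08),
           plate_amp = stats::rnorm(1, 0.40, 0.05),
           plate_z = stats::rnorm(1, 0.28, 0.02),
           roundness_gain = 0)
    })
    crops <- lapply(seq_len(n), function(i) {
      render_crop(phantom_latents(t1 = t1[i]), grid_shape = grid_shape,
                  seed = derive_seed(seed, "angle_crop", i),
                  noise_sd = noise_sd, blur_fwhm = blur_fwhm,
                  offset = offs[i, ], anatomy = anat[[i]],
                  subject_id = sprintf("angle_%04d", i))
    })
    list(crops = crops,
         scores = round_prediction(2 * t1, "C1"),
         latents = t1)
  })
}

#' Write a phantom cohort to disk
#'
#' One NIfTI file per subject x hemisphere plus `ratings_observed.tsv`,
#' `ratings_truth.tsv` and a `spec.json` sidecar.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (hemi in c("left", "right")) {
    for (cr in cohort$crops[[hemi]]) {
      fn <- file.path(dir, sprintf("%s_%s.nii.gz", attr(cr, "subject_id"), hemi))
      RNifti::writeNifti(unclass(as.array(cr)), fn)
    }
  }
  write_ratings(cohort$ratings_observed, file.path(dir, "ratings_observed.tsv"))
  write_ratings(cohort$ratings_truth, file.path(dir, "ratings_truth.tsv"))
  jsonlite::write_json(unclass(cohort$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
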