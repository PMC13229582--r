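#' Specification of a synthetic resting-state cohort
#'
#' Collects every tunable of the synthetic-cohort generator. The defaults
#' emulate the study conditions the package is designed around: 240
#' timepoints at TR = 2 s, 16 ROIs, a planted correlation of -0.3 between
#' the multi-voxel velocity driver and the latent self-recovery factor, and
#' a weak (-0.15) link between the latent general-resilience factor and the
#' amplitude of a globally coherent signal that drives ROI-mean variability.
#'
#' @param n_subjects number of subjects.
#' @param n_voxels voxels per subject (split evenly over `n_rois`).
#' @param n_timepoints timepoints per subject (>= 2).
#' @param tr_seconds repetition time, seconds.
#' @param effect_r planted correlation, in `[-1, 1]`, between the velocity
#'   driver (monotone in the mean transition velocity) and the latent
#'   self-recovery factor. Negative values plant the "smaller transitions,
#'   higher self-recovery" direction.
#' @param general_link_r planted correlation between the latent general
#'   factor and the global-coherence driver of ROI-mean variability.
#' @param driver_cor correlation between the subject-level noise parts of
#'   the two neural drivers; gives the positive correlation between the
#'   velocity and rMSSD metrics seen in real data.
#' @param fd_scale scale (mm) of simulated head-motion drift.
#' @param n_voxels_sd SD of the per-subject voxel count around `n_voxels`
#'   (0 gives every subject the same ROI size); the empirical distribution
#'   of subject-space ROI sizes is study-specific, so it is exposed as a
#'   parameter rather than fixed.
#' @param snr ratio of per-voxel signal variance to white-noise variance.
#' @param m latent dimensionality of the AR(1) state process.
#' @param n_rois number of pseudo-ROIs the voxels are partitioned into.
#' @param seed master seed; identical specs (including seed) reproduce
#'   byte-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_subjects, n_voxels = 96L, n_timepoints = 240L,
                        tr_seconds = 2, effect_r = -0.3,
                        general_link_r = -0.15, driver_cor = 0.3,
                        fd_scale = 0.1, n_voxels_sd = 0, snr = 2, m = 3L,
                        n_rois = 16L, seed = 1L) {
  spec <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_voxels = check_count(n_voxels, "n_voxels", min = 2L),
    n_timepoints = check_count(n_timepoints, "n_timepoints", min = 2L),
    tr_seconds = check_scalar(tr_seconds, "tr_seconds", lower = 1e-9),
    effect_r = check_scalar(effect_r, "effect_r", lower = -1, upper = 1),
    general_link_r = check_scalar(general_link_r, "general_link_r",
                                  lower = -1, upper = 1),
    driver_cor = check_scalar(driver_cor, "driver_cor", lower = -1, upper = 1),
    fd_scale = check_scalar(fd_scale, "fd_scale", lower = 0),
    n_voxels_sd = check_scalar(n_voxels_sd, "n_voxels_sd", lower = 0),
    snr = check_scalar(snr, "snr", lower = 1e-9),
    m = check_count(m, "m"),
    n_rois = check_count(n_rois, "n_rois"),
    seed = check_seed(seed))
  if (spec$n_voxels < spec$n_rois) {
    stop_param("`n_voxels` must be at least `n_rois`")
  }
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d subjects, %d voxels x %d timepoints ",
                     "(TR %gs), effect_r = %g, seed = %d\n"),
              x$n_subjects, x$n_voxels, x$n_timepoints, x$tr_seconds,
              x$effect_r, x$seed))
  invisible(x)
}

# Latent AR(1) process with unit marginal variance: d series of length n.
ar1_series <- function(n, rho, d = 1L) {
  x <- matrix(0, d, n)
  x[, 1L] <- rnorm(d)
  if (n > 1L) {
    innov_sd <- sqrt(1 - rho^2)
    for (t in 2:n) x[, t] <- rho * x[, t - 1L] + rnorm(d, sd = innov_sd)
  }
  x
}

#' Simulate one subject's voxel-by-time matrix
#'
#' Generates a low-rank latent AR(1) state process (`m` latent dimensions
#' with persistence `rho` and unit marginal variance) mapped through a fixed
#' random voxel-loading matrix with unit-norm rows, plus optional globally
#' coherent signal and white voxel noise at the stated signal-to-noise
#' ratio. Column `t` is the multi-voxel state vector at timepoint `t`.
#'
#' @param rho AR(1) persistence of the latent state process, in `[0, 1)`.
#'   Higher values mean more autocorrelated consecutive states and hence
#'   smaller transition velocities at fixed marginal variance.
#' @param n_voxels,n_timepoints matrix dimensions.
#' @param snr per-voxel signal-to-noise variance ratio (`Inf` allowed for
#'   noise-free output).
#' @param seed RNG seed (determinism contract: same arguments, same matrix).
#' @param m latent dimensionality.
#' @param global_amp amplitude of a shared AR(1) component added equally to
#'   all voxels (drives ROI-mean coherence); 0 disables it.
#' @param global_rho persistence of the shared component.
#' @param tr_seconds repetition time stored on the result.
#' @return A [state_matrix()] of dimension `n_voxels` x `n_timepoints`.
#' @examples
#' m <- simulate_voxel_timeseries(rho = 0.6, n_voxels = 20,
#'                                n_timepoints = 50, snr = 2, seed = 1)
#' @export
simulate_voxel_timeseries <- function(rho, n_voxels, n_timepoints, snr,
                                      seed, m = 3L, global_amp = 0,
                                      global_rho = 0.3, tr_seconds = 2) {
  check_scalar(rho, "rho", lower = 0, upper = 1, strict_upper = TRUE)
  n_voxels <- check_count(n_voxels, "n_voxels", min = 2L)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2L)
  if (length(snr) != 1L || is.na(snr) || snr <= 0) {
    stop_param("`snr` must be a single positive number (Inf allowed)")
  }
  m <- check_count(m, "m")
  check_scalar(global_amp, "global_amp", lower = 0)
  check_scalar(global_rho, "global_rho", lower = 0, upper = 1,
               strict_upper = TRUE)
  seed <- check_seed(seed)
  with_seed(seed, {
    latent <- ar1_series(n_timepoints, rho, d = m)
    load <- matrix(rnorm(n_voxels * m), n_voxels, m)
    load <- load / sqrt(rowSums(load^2))
    values <- load %*% latent
    if (global_amp > 0) {
      shared <- ar1_series(n_timepoints, global_rho, d = 1L)
      values <- values + global_amp * matrix(shared, n_voxels, n_timepoints,
                                             byrow = TRUE)
    }
    if (is.finite(snr)) {
      values <- values + matrix(rnorm(n_voxels * n_timepoints,
                                      sd = 1 / sqrt(snr)),
                                n_voxels, n_timepoints)
    }
    state_matrix(values, tr_seconds = tr_seconds)
  })
}

#' Simulate a six-parameter head-motion trace
#'
#' Produces a realignment-parameter table (3 translations in mm, 3 rotations
#' in degrees) as slowly drifting seeded random walks whose framewise
#' displacement scales with `fd_scale`, plus exactly `n_spikes` single-frame
#' excursions exceeding the motion-exclusion threshold. Spikes are placed at
#' random interior timepoints (never the first frame, where framewise
#' displacement is undefined).
#'
#' @param n_timepoints number of frames.
#' @param fd_scale target mean framewise displacement of the drift, mm;
#'   0 gives an all-zero trace.
#' @param n_spikes number of above-threshold excursions to plant.
#' @param seed RNG seed.
#' @param spike_amplitude_mm translation amplitude of each planted spike;
#'   must exceed the 3.4375 mm exclusion threshold to be flagged.
#' @return Numeric `n_timepoints` x 6 matrix with columns
#'   `trans_x/y/z` (mm) and `rot_x/y/z` (degrees).
#' @export
simulate_motion <- function(n_timepoints, fd_scale, n_spikes = 0L, seed = 1L,
                            spike_amplitude_mm = 5) {
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2L)
  check_scalar(fd_scale, "fd_scale", lower = 0)
  n_spikes <- check_count(n_spikes, "n_spikes", min = 0L)
  check_scalar(spike_amplitude_mm, "spike_amplitude_mm", lower = 0)
  seed <- check_seed(seed)
  if (n_spikes > n_timepoints - 1L) {
    stop_param("more spikes requested than interior timepoints available")
  }
  with_seed(seed, {
    trace <- matrix(0, n_timepoints, 6L,
                    dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                            "rot_x", "rot_y", "rot_z")))
    if (fd_scale > 0) {
      # mean |N(0, s)| = s * sqrt(2/pi); six parameters contribute to FD,
      # rotations after conversion to arc length on a 50 mm sphere.
      step_mm <- fd_scale / (6 * sqrt(2 / pi))
      step_deg <- step_mm * 180 / (50 * pi)
      for (j in 1:3) {
        trace[, j] <- pmin(pmax(cumsum(c(0, rnorm(n_timepoints - 1L,
                                                  sd = step_mm))), -2), 2)
      }
      for (j in 4:6) {
        trace[, j] <- pmin(pmax(cumsum(c(0, rnorm(n_timepoints - 1L,
                                                  sd = step_deg))), -2), 2)
      }
    }
    if (n_spikes > 0L) {
      at <- sample(2:n_timepoints, n_spikes)
      trace[at, "trans_x"] <- trace[at, "trans_x"] + spike_amplitude_mm
    }
    trace
  })
}

#' Default item-loading design of the questionnaire generator
#'
#' Standardised loadings of each instrument's items on the three latent
#' factors (general resilience, self-recovery, external support), with unit
#' item uniqueness. All instruments share the general factor; the BRS adds
#' the self-recovery factor (its defining construct), the RSA intra-personal
#' subscales add a weaker self-recovery loading, and the RSA inter-personal
#' subscales add the support factor. Under this design the three scale
#' totals reproduce the qualitative correlation and principal-component
#' structure seen in real resilience batteries: a dominant all-positive PC1
#' and a PC2 contrasting BRS against RSA.
#'
#' @return Named list of loading vectors `c(general, selfrecovery, support)`
#'   per item family, plus the `noise_sd` of the item uniqueness.
#' @export
default_item_loadings <- function() {
  list(cdrisc = c(general = 0.75, selfrecovery = 0, support = 0),
       brs = c(general = 0.50, selfrecovery = 0.65, support = 0),
       rsa_intra = c(general = 0.60, selfrecovery = 0.30, support = 0),
       rsa_inter = c(general = 0.60, selfrecovery = 0, support = 0.55),
       noise_sd = 1)
}

discretize_items <- function(y, sd_theory, n_levels, offset = 0L) {
  cuts <- qnorm(seq_len(n_levels - 1L) / n_levels)
  as.integer(findInterval(y / sd_theory, cuts)) + offset
}

#' Simulate item-level questionnaire responses for one subject
#'
#' Items are latent-continuous values (factor loadings from `loadings` plus
#' Gaussian uniqueness) discretised to each instrument's Likert range using
#' thresholds at equal-probability quantiles of the latent normal, so the
#' marginal item distribution is uniform at zero effect. BRS items are
#' generated already in scored orientation (reverse-keying is exercised by
#' the scoring module, not the generator).
#'
#' @param truth list or one-row data frame with `latent_general`,
#'   `latent_selfrecovery` and `latent_support` (standardised factors).
#' @param seed RNG seed.
#' @param loadings loading design, see [default_item_loadings()].
#' @param subscale_map RSA item-to-subscale map, see [rsa_subscale_map()].
#' @param noise_sd item uniqueness SD; 0 gives deterministic items (useful
#'   for ceiling/floor checks).
#' @return List with integer vectors `cdrisc` (25 items, 0-4), `brs`
#'   (6 items, 1-5) and `rsa` (29 items, 1-7).
#' @export
simulate_item_responses <- function(truth, seed = 1L,
                                    loadings = default_item_loadings(),
                                    subscale_map = rsa_subscale_map(),
                                    noise_sd = loadings$noise_sd) {
  g <- truth$latent_general
  sr <- truth$latent_selfrecovery
  sup <- truth$latent_support
  if (any(!is.finite(c(g, sr, sup)))) {
    stop_param("latent factors must be finite")
  }
  check_scalar(noise_sd, "noise_sd", lower = 0)
  seed <- check_seed(seed)
  lat <- c(g, sr, sup)
  item_block <- function(lambda, k, n_levels, offset) {
    mu <- sum(lambda * lat)
    sd_theory <- sqrt(sum(lambda^2) + noise_sd^2)
    y <- mu + rnorm(k, sd = noise_sd)
    discretize_items(y, sd_theory, n_levels, offset)
  }
  with_seed(seed, {
    cdrisc <- item_block(loadings$cdrisc, 25L, 5L, offset = 0L)
    brs <- item_block(loadings$brs, 6L, 5L, offset = 1L)
    intra <- subscale_map$subscale %in% c("personal_strength",
                                          "future_structured_style")
    rsa <- integer(29L)
    rsa[intra] <- item_block(loadings$rsa_intra, sum(intra), 7L, offset = 1L)
    rsa[!intra] <- item_block(loadings$rsa_inter, sum(!intra), 7L,
                              offset = 1L)
    list(cdrisc = cdrisc, brs = brs, rsa = rsa)
  })
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Draws independent standardised latent factors per subject (general
#' resilience, self-recovery, external support), plants the velocity and
#' global-coherence drivers at the correlations stated in the cohort
#' specification,
#' and generates per-subject voxel matrices, motion traces and item-level
#' questionnaire responses. The mapping from the velocity driver `v` to the
#' AR(1) persistence is `rho = clamp(0.5 - 0.2 v, 0.02, 0.97)`, and the
#' global-coherence amplitude is `0.3 exp(0.5 w)` in the driver `w`, so the
#' mean transition velocity is monotone-increasing in `v` and the ROI-mean
#' variability metrics are monotone-increasing in `w`.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `synthetic_cohort`: list with `spec`, `truth`
#'   (data frame: subject, latent factors, drivers, persistence_rho,
#'   global_amp), `items` (one row per subject, columns `cdrisc_01..25`,
#'   `brs_01..06`, `rsa_01..29`), `matrices` (list of [state_matrix()]),
#'   `motion` (list of motion tables) and `roi_assignment` (per-subject
#'   factor mapping voxels to the pseudo-ROIs).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_seed(spec$seed, {
    g <- rnorm(n); sr <- rnorm(n); sup <- rnorm(n)
    e_v <- rnorm(n)
    e_w <- spec$driver_cor * e_v + sqrt(1 - spec$driver_cor^2) * rnorm(n)
    r_v <- spec$effect_r
    r_w <- spec$general_link_r
    v <- r_v * sr + sqrt(1 - r_v^2) * e_v
    w <- r_w * g + sqrt(1 - r_w^2) * e_w
    rho <- pmin(pmax(0.5 - 0.2 * v, 0.02), 0.97)
    amp <- 0.3 * exp(0.5 * w)
    nvox <- pmax(spec$n_rois,
                 round(rnorm(n, spec$n_voxels, spec$n_voxels_sd)))
    sub_seed <- sample.int(2^31 - 2^20, n)
  })
  truth <- data.frame(subject = sprintf("sub%03d", seq_len(n)),
                      latent_general = g, latent_selfrecovery = sr,
                      latent_support = sup, velocity_driver = v,
                      variance_driver = w, persistence_rho = rho,
                      global_amp = amp, n_voxels = nvox, seed = sub_seed,
                      stringsAsFactors = FALSE)
  matrices <- vector("list", n)
  motion <- vector("list", n)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    matrices[[i]] <- simulate_voxel_timeseries(
      rho = rho[i], n_voxels = nvox[i],
      n_timepoints = spec$n_timepoints, snr = spec$snr,
      seed = sub_seed[i], m = spec$m, global_amp = amp[i],
      tr_seconds = spec$tr_seconds)
    motion[[i]] <- simulate_motion(spec$n_timepoints, spec$fd_scale,
                                   n_spikes = 0L, seed = sub_seed[i] + 1L)
    resp <- simulate_item_responses(truth[i, ], seed = sub_seed[i] + 2L)
    items[[i]] <- c(setNames(resp$cdrisc, sprintf("cdrisc_%02d", 1:25)),
                    setNames(resp$brs, sprintf("brs_%02d", 1:6)),
                    setNames(resp$rsa, sprintf("rsa_%02d", 1:29)))
  }
  names(matrices) <- names(motion) <- truth$subject
  items <- as.data.frame(do.call(rbind, items))
  items <- cbind(data.frame(subject = truth$subject,
                            stringsAsFactors = FALSE), items)
  roi_assignment <- lapply(nvox, function(k) {
    factor(rep(seq_len(spec$n_rois), length.out = k))
  })
  names(roi_assignment) <- truth$subject
  structure(list(spec = spec, truth = truth, items = items,
                 matrices = matrices, motion = motion,
                 roi_assignment = roi_assignment),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d voxels x %d timepoints)\n",
              x$spec$n_subjects, x$spec$n_voxels, x$spec$n_timepoints))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes item responses and ground truth as CSV, motion traces as 6-column
#' whitespace-delimited text, and voxel matrices as serialized arrays, under
#' `dir`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(items = file.path(dir, "items.csv"),
             truth = file.path(dir, "ground_truth.csv"))
  write.csv(cohort$items, paths[["items"]], row.names = FALSE)
  write.csv(cohort$truth, paths[["truth"]], row.names = FALSE)
  mdir <- file.path(dir, "motion"); dir.create(mdir, showWarnings = FALSE)
  adir <- file.path(dir, "matrices"); dir.create(adir, showWarnings = FALSE)
  for (s in cohort$truth$subject) {
    write_motion(cohort$motion[[s]], file.path(mdir, paste0(s, "_rp.txt")))
    write_state_matrix(cohort$matrices[[s]],
                       file.path(adir, paste0(s, ".rds")))
  }
  invisible(paths)
}
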