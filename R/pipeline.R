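#' Configuration for an end-to-end pipeline run
#'
#' Validates every stage parameter up front (schema errors are raised
#' before any computation), and fully determines a run together with its
#' seeds: identical configurations reproduce identical outputs.
#'
#' @param spec a [cohort_spec()] for synthetic input, or `NULL` when
#'   `input_dir` points at a cohort directory written by [write_cohort()].
#' @param input_dir optional directory with `items.csv`, `motion/`,
#'   `matrices/` (as written by [write_cohort()]).
#' @param n_dummy dummy volumes to discard in conditioning.
#' @param band bandpass edges, Hz; must respect the Nyquist limit.
#' @param condition run the conditioning stage (confound regression,
#'   detrend, bandpass) on each subject's matrix.
#' @param max_translation_mm,max_rotation_deg motion-exclusion thresholds.
#' @param k_candidates,stress_threshold,restarts,maxit embedding controls.
#' @param brs_reverse_keyed passed to [score_scales()]; the generator
#'   writes BRS items already in scored orientation.
#' @param fdr_alpha significance level applied to FDR-adjusted p-values.
#' @param covariates covariate columns for the adjusted correlations.
#' @param tr_seconds repetition time (defaults from `spec`).
#' @param seed master analysis seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = NULL, input_dir = NULL, n_dummy = 0L,
                            band = c(0.009, 0.08), condition = TRUE,
                            max_translation_mm = 3.4375,
                            max_rotation_deg = 3,
                            k_candidates = c(2L, 3L, 4L),
                            stress_threshold = 0.10, restarts = 8L,
                            maxit = 200L, brs_reverse_keyed = FALSE,
                            fdr_alpha = 0.05,
                            covariates = c("fd_mean", "roi_size"),
                            tr_seconds = NULL, seed = 1L) {
  if (is.null(spec) && is.null(input_dir)) {
    stop_param("supply a cohort `spec` or an `input_dir`")
  }
  if (!is.null(spec) && !inherits(spec, "cohort_spec")) {
    stop_param("`spec` must be a cohort_spec")
  }
  tr <- tr_seconds %||% (if (!is.null(spec)) spec$tr_seconds else 2)
  if (length(band) != 2L || any(!is.finite(band)) || band[1L] <= 0 ||
      band[1L] >= band[2L]) {
    stop_param("`band` must be two increasing positive frequencies")
  }
  if (band[2L] >= 1 / (2 * tr)) {
    stop_param(sprintf("band high edge %g Hz is at or above Nyquist (%g Hz)",
                       band[2L], 1 / (2 * tr)))
  }
  structure(list(spec = spec, input_dir = input_dir,
                 n_dummy = check_count(n_dummy, "n_dummy", min = 0L),
                 band = as.numeric(band), condition = isTRUE(condition),
                 max_translation_mm = check_scalar(max_translation_mm,
                                                   "max_translation_mm", 0),
                 max_rotation_deg = check_scalar(max_rotation_deg,
                                                 "max_rotation_deg", 0),
                 k_candidates = as.integer(k_candidates),
                 stress_threshold = check_scalar(stress_threshold,
                                                 "stress_threshold", 0),
                 restarts = check_count(restarts, "restarts"),
                 maxit = check_count(maxit, "maxit"),
                 brs_reverse_keyed = isTRUE(brs_reverse_keyed),
                 fdr_alpha = check_scalar(fdr_alpha, "fdr_alpha", 0, 1),
                 covariates = as.character(covariates),
                 tr_seconds = tr, seed = check_seed(seed)),
            class = "pipeline_config")
}

read_cohort_dir <- function(dir) {
  items <- read.csv(file.path(dir, "items.csv"), stringsAsFactors = FALSE)
  subjects <- as.character(items$subject)
  motion <- lapply(subjects, function(s) {
    read_motion(file.path(dir, "motion", paste0(s, "_rp.txt")))
  })
  matrices <- lapply(subjects, function(s) {
    read_state_matrix(file.path(dir, "matrices", paste0(s, ".rds")))
  })
  names(motion) <- names(matrices) <- subjects
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) {
    read.csv(truth_path, stringsAsFactors = FALSE)
  } else NULL
  roi_assignment <- lapply(matrices, function(m) {
    factor(rep(1:16, length.out = nrow(m)))
  })
  structure(list(spec = NULL, truth = truth, items = items,
                 matrices = matrices, motion = motion,
                 roi_assignment = roi_assignment),
            class = "synthetic_cohort")
}

#' Analyse a cohort: dynamics metrics, scale scores, PCA, associations
#'
#' The analysis backbone shared by [run_pipeline()] and the package tests:
#' motion exclusion, optional conditioning, per-subject state dynamics,
#' questionnaire scoring, the main (three scale totals) and secondary
#' (five RSA subscales + CD-RISC + BRS) PCAs, and the metric-by-measure
#' association grids (one FDR family per dynamics metric).
#'
#' @param cohort a `synthetic_cohort` (from [simulate_cohort()] or
#'   [read_cohort_dir] via [run_pipeline()]).
#' @param config a [pipeline_config()].
#' @return List with `table` (one row per retained subject: metrics,
#'   scores, PC scores), `metrics`, `scores`, `pca_main`, `pca_sub`,
#'   `exclusion`, `grids` (list of [pearson_grid()] tables), `adjusted`
#'   (covariate-adjusted headline correlations) and `cross_metrics`.
#' @export
analyze_cohort <- function(cohort, config) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(config, "pipeline_config"))
  part <- exclude_by_motion(cohort$motion,
                            max_translation_mm = config$max_translation_mm,
                            max_rotation_deg = config$max_rotation_deg)
  keep <- part$retained
  if (length(keep) < 4L) stop_param("fewer than 4 subjects retained")

  metrics <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    s <- keep[i]
    mat <- cohort$matrices[[s]]
    motion <- cohort$motion[[s]]
    fd_mean <- mean(compute_fd(motion))
    if (config$condition) {
      mat <- condition_series(mat, motion = motion, n_dummy = config$n_dummy,
                              band = config$band,
                              tr_seconds = attr(mat, "tr_seconds"))
      if (config$n_dummy > 0L) {
        motion <- discard_dummies(motion, config$n_dummy, margin = "rows")
        fd_mean <- mean(compute_fd(motion))
      }
    } else if (config$n_dummy > 0L) {
      mat <- discard_dummies(mat, config$n_dummy)
      motion <- discard_dummies(motion, config$n_dummy, margin = "rows")
      fd_mean <- mean(compute_fd(motion))
    }
    dyn <- state_dynamics(mat, roi_assignment = cohort$roi_assignment[[s]],
                          fd_mean = fd_mean,
                          k_candidates = config$k_candidates,
                          stress_threshold = config$stress_threshold,
                          restarts = config$restarts,
                          seed = config$seed + i, maxit = config$maxit)
    dyn$subject <- s
    metrics[[i]] <- dyn
  }
  metrics <- do.call(rbind, metrics)
  metrics <- metrics[, c("subject", setdiff(names(metrics), "subject"))]

  scores <- score_scales(cohort$items,
                         brs_reverse_keyed = config$brs_reverse_keyed)
  scores <- scores[scores$subject %in% keep, , drop = FALSE]

  pca_main <- pca_scales(scores, measures = c("cdrisc", "brs", "rsa"))
  sub_cols <- paste0("rsa_", c("family_cohesion", "social_competence",
                               "social_resources", "personal_strength",
                               "future_structured_style"))
  pca_sub <- pca_scales(scores, measures = c("cdrisc", "brs", sub_cols))

  tab <- merge(metrics, scores, by = "subject", sort = TRUE)
  tab <- tab[match(sort(keep), tab$subject), , drop = FALSE]
  sc_order <- match(tab$subject, scores$subject)
  tab$pc1 <- pca_main$scores[sc_order, 1L]
  tab$pc2 <- pca_main$scores[sc_order, 2L]
  tab$pc1_sub <- pca_sub$scores[sc_order, 1L]
  tab$pc2_sub <- pca_sub$scores[sc_order, 2L]
  rownames(tab) <- NULL

  measures <- c("cdrisc", "brs", "rsa", "pc1", "pc2")
  grids <- list()
  for (metric in c("mu_v", "rmssd", "sd")) {
    if (all(is.finite(tab[[metric]]))) {
      grids[[metric]] <- pearson_grid(tab, metric, measures,
                                      family = paste0(metric, "_main"))
    }
  }
  covars <- config$covariates[vapply(config$covariates, function(cv) {
    cv %in% names(tab) && sd(tab[[cv]]) > 0
  }, logical(1))]
  if (length(covars) < length(config$covariates)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(setdiff(config$covariates, covars),
                          collapse = ", ")), call. = FALSE)
  }
  adjusted <- if (length(covars) > 0L) {
    do.call(rbind, lapply(names(grids), function(metric) {
      do.call(rbind, lapply(c("pc1", "pc2"), function(ms) {
        adjusted_correlation(tab, metric, ms, covariates = covars)
      }))
    }))
  } else NULL
  cross_metrics <- cross_metric_summary(tab, c("mu_v", "rmssd", "sd"))

  list(table = tab, metrics = metrics, scores = scores,
       pca_main = pca_main, pca_sub = pca_sub, exclusion = part,
       grids = grids, adjusted = adjusted, cross_metrics = cross_metrics)
}

#' Run the full pipeline and write a run directory with a manifest
#'
#' Chains synthesis (or cohort loading), motion exclusion, conditioning,
#' state dynamics, scale scoring, PCA and the association grids, writing
#' every table as CSV plus a JSON manifest recording stage order,
#' parameters, seeds and software versions. Because every stochastic stage
#' is seeded from the configuration, the manifest suffices to re-execute
#' any stage bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return Object of class `pipeline_run`: the [analyze_cohort()] result
#'   plus `paths` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (!is.null(config$input_dir)) {
    read_cohort_dir(config$input_dir)
  } else {
    simulate_cohort(config$spec)
  }
  res <- analyze_cohort(cohort, config)

  paths <- c(metrics = file.path(out_dir, "metrics.csv"),
             scores = file.path(out_dir, "scores.csv"),
             cohort = file.path(out_dir, "cohort.csv"),
             associations = file.path(out_dir, "associations.csv"),
             adjusted = file.path(out_dir, "adjusted.csv"),
             exclusion = file.path(out_dir, "exclusion.csv"),
             pca = file.path(out_dir, "pca.json"),
             manifest = file.path(out_dir, "manifest.json"))
  write.csv(res$metrics, paths[["metrics"]], row.names = FALSE)
  write.csv(res$scores, paths[["scores"]], row.names = FALSE)
  write.csv(res$table, paths[["cohort"]], row.names = FALSE)
  write.csv(do.call(rbind, lapply(res$grids, as.data.frame)),
            paths[["associations"]], row.names = FALSE)
  write.csv(res$adjusted, paths[["adjusted"]], row.names = FALSE)
  write.csv(res$exclusion$flags, paths[["exclusion"]], row.names = FALSE)
  pca_report <- list(
    main = list(loadings = res$pca_main$loadings,
                variance_explained = res$pca_main$variance_explained),
    secondary = list(loadings = res$pca_sub$loadings,
                     variance_explained = res$pca_sub$variance_explained))
  jsonlite::write_json(pca_report, paths[["pca"]], digits = NA,
                       matrix = "rowmajor", auto_unbox = TRUE)
  manifest <- list(
    stages = c("simulate_or_load", "exclude_by_motion",
               if (config$condition) "condition_series",
               "state_dynamics", "score_scales", "pca_scales",
               "pearson_grid", "adjusted_correlation"),
    parameters = config[setdiff(names(config), c("spec", "input_dir"))],
    cohort_spec = if (!is.null(config$spec)) {
      unclass(config$spec)
    } else list(input_dir = config$input_dir),
    n_retained = length(res$exclusion$retained),
    n_excluded = length(res$exclusion$excluded),
    versions = list(statevel = as.character(utils::packageVersion("statevel")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, paths[["manifest"]], digits = NA,
                       auto_unbox = TRUE, null = "null")
  structure(c(res, list(paths = paths, manifest = manifest,
                        config = config)),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d subjects retained, %d excluded\n",
              length(x$exclusion$retained), length(x$exclusion$excluded)))
  cat("outputs:\n")
  for (p in x$paths) cat("  ", p, "\n")
  invisible(x)
}
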