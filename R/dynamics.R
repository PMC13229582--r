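#' Grand z-normalisation of a voxel matrix
#'
#' Normalises the whole voxels x timepoints matrix to its grand mean and
#' grand SD (computed jointly over all entries), putting every state vector
#' in SD units. Per-voxel normalisation is available behind `per_voxel` for
#' sensitivity analyses.
#'
#' @param matrix_ a [state_matrix()] or plain matrix.
#' @param per_voxel if `TRUE`, z-score each voxel series separately
#'   instead of using the grand moments.
#' @return A [state_matrix()] with the `normalized` flag set.
#' @export
znormalize_matrix <- function(matrix_, per_voxel = FALSE) {
  vals <- unclass(matrix_)
  attributes(vals) <- attributes(vals)["dim"]
  if (per_voxel) {
    sds <- apply(vals, 1L, sd)
    if (any(sds == 0)) stop_param("constant voxel series: degenerate input")
    out <- (vals - rowMeans(vals)) / sds
  } else {
    s <- sd(as.vector(vals))
    if (s == 0) stop_param("constant matrix: degenerate input")
    out <- (vals - mean(vals)) / s
  }
  if (inherits(matrix_, "state_matrix")) {
    restate(out, matrix_, normalized = TRUE)
  } else {
    state_matrix(out, normalized = TRUE)
  }
}

#' Pairwise Euclidean distances between state vectors
#'
#' Distances between the column state vectors of a z-normalised matrix;
#' the dissimilarity input to the MDS embedding.
#'
#' @param matrix_ a z-normalised [state_matrix()].
#' @return A `stats::dist` object over timepoints.
#' @export
state_distances <- function(matrix_) {
  if (!isTRUE(attr(matrix_, "normalized"))) {
    stop_param("matrix must be z-normalised before computing state distances")
  }
  stats::dist(t(unclass(matrix_)))
}

#' Embed states by non-metric MDS with stress-based dimensionality
#'
#' Fits non-metric MDS (Kruskal stress-1, via [vegan::monoMDS()]) at each
#' candidate dimension with `restarts` seeded initialisations — the first
#' from classical (metric) scaling, the rest random — keeping the
#' lowest-stress solution per dimension (ties favour the metric start).
#' The chosen dimension is the smallest candidate whose stress falls below
#' `stress_threshold`; if none does, the candidate with minimal stress is
#' used. Because the NMDS criterion is scale-invariant, the winning
#' configuration is rescaled by the least-squares factor that matches the
#' embedded to the input dissimilarities, so coordinates (and the
#' transition velocities derived from them) stay in the dissimilarity
#' units (SD). Identical inputs and seed give bitwise-identical
#' coordinates.
#'
#' @param distances a `dist` object (see [state_distances()]).
#' @param k_candidates candidate embedding dimensions.
#' @param stress_threshold stress-1 acceptance cut (0.10 is the
#'   conventional "fair" value).
#' @param restarts number of initialisations per dimension (1 = metric
#'   start only).
#' @param seed RNG seed for the random initialisations.
#' @param maxit maximum stress-majorisation iterations per fit.
#' @return Object of class `state_embedding`: `points` (n x k matrix),
#'   `k`, `stress`, `stress_by_k`, `converged`, `seed`, `n`.
#' @export
embed_states <- function(distances, k_candidates = c(2L, 3L, 4L),
                         stress_threshold = 0.10, restarts = 8L, seed = 1L,
                         maxit = 200L) {
  if (!inherits(distances, "dist")) stop_param("`distances` must be a dist")
  n <- attr(distances, "Size")
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (any(k_candidates < 1L) || any(k_candidates >= n)) {
    stop_param("candidate dimensions must be in [1, n_timepoints)")
  }
  restarts <- check_count(restarts, "restarts", min = 1L)
  check_scalar(stress_threshold, "stress_threshold", lower = 0)
  seed <- check_seed(seed)

  # all-zero distances: every state coincides; embedding is a single point
  if (max(distances) == 0) {
    k <- k_candidates[1L]
    return(structure(list(points = matrix(0, n, k), k = k, stress = 0,
                          stress_by_k = setNames(rep(0, length(k_candidates)),
                                                 k_candidates),
                          converged = TRUE, seed = seed, n = n),
                     class = "state_embedding"))
  }

  fits <- vector("list", length(k_candidates))
  stress_by_k <- setNames(rep(NA_real_, length(k_candidates)), k_candidates)
  metric_start <- function(k) {
    y <- suppressWarnings(stats::cmdscale(distances, k = k))
    if (ncol(y) < k) y <- cbind(y, matrix(0, n, k - ncol(y)))
    unname(y)
  }
  for (ki in seq_along(k_candidates)) {
    k <- k_candidates[ki]
    best <- NULL
    with_seed(seed + 131L * k, {
      for (r in seq_len(restarts)) {
        y0 <- if (r == 1L) metric_start(k) else matrix(rnorm(n * k), n, k)
        fit <- vegan::monoMDS(distances, y = y0, k = k, model = "global",
                              maxit = maxit)
        if (is.null(best) || fit$stress < best$stress - 1e-12) best <- fit
      }
    })
    fits[[ki]] <- best
    stress_by_k[ki] <- best$stress
  }
  if (all(!is.finite(stress_by_k))) {
    stop_param("NMDS failed to produce a finite stress at any dimension")
  }
  ok <- stress_by_k < stress_threshold
  pick <- if (any(ok)) which(ok)[1L] else which.min(stress_by_k)
  best <- fits[[pick]]
  pts <- unname(best$points)
  d_emb <- stats::dist(pts)
  scale_b <- sum(distances * d_emb) / sum(d_emb^2)
  pts <- pts * scale_b
  structure(list(points = pts, k = k_candidates[pick],
                 stress = stress_by_k[[pick]], stress_by_k = stress_by_k,
                 converged = TRUE, seed = seed, n = n),
            class = "state_embedding")
}

#' @export
print.state_embedding <- function(x, ...) {
  cat(sprintf("<state_embedding> n = %d states in k = %d dims, stress = %.4f\n",
              x$n, x$k, x$stress))
  cat("  stress by k:",
      paste(sprintf("%s: %.4f", names(x$stress_by_k), x$stress_by_k),
            collapse = ", "), "\n")
  invisible(x)
}

#' Transition velocities between consecutive embedded states
#'
#' The velocity of the transition from state `t` to `t + 1` is the
#' Euclidean distance between their embedded coordinates. With states in
#' SD units sampled every TR, velocities are in SD per TR (SD/2 s at
#' TR = 2 s).
#'
#' @param embedding a [embed_states()] result, or a timepoints x k
#'   coordinate matrix.
#' @return Numeric vector of `n - 1` non-negative velocities.
#' @export
transition_velocities <- function(embedding) {
  coords <- if (inherits(embedding, "state_embedding")) {
    embedding$points
  } else as.matrix(embedding)
  if (nrow(coords) < 2L) stop_param("embedding needs at least 2 states")
  steps <- diff(coords)
  sqrt(rowSums(steps^2))
}

#' Mean transition velocity
#'
#' Arithmetic mean of the `n - 1` transition velocities (the per-subject
#' summary metric, e.g. DMN muV).
#'
#' @param velocities numeric vector of transition velocities.
#' @param n optional timepoint count for a length check
#'   (`length(velocities)` must equal `n - 1`).
#' @return A single non-negative number.
#' @export
mean_transition_velocity <- function(velocities, n = NULL) {
  if (length(velocities) == 0L) stop_param("empty velocity series")
  if (!is.null(n) && length(velocities) != n - 1L) {
    stop_param(sprintf("expected %d velocities for n = %d timepoints, got %d",
                       n - 1L, n, length(velocities)))
  }
  mean(velocities)
}

#' Across-ROI mean z-score series
#'
#' Each ROI-mean time series is z-scored across time (mean 0, SD 1), and
#' the z-scored series are then averaged across ROIs at each timepoint.
#' The resulting series is the input to the rMSSD and SD variability
#' metrics.
#'
#' @param roi_series ROIs x timepoints matrix of ROI-mean signals.
#' @param scale_rois if `FALSE`, skip the per-ROI z-scoring and average the
#'   raw series (sensitivity-analysis alternative).
#' @return Numeric vector of length `n_timepoints`.
#' @export
roi_mean_zseries <- function(roi_series, scale_rois = TRUE) {
  roi_series <- as.matrix(roi_series)
  if (ncol(roi_series) < 2L) stop_param("need at least 2 timepoints")
  if (any(!is.finite(roi_series))) stop_param("non-finite ROI series")
  if (scale_rois) {
    sds <- apply(roi_series, 1L, sd)
    if (any(sds == 0)) {
      bad <- which(sds == 0)[1L]
      nm <- rownames(roi_series)[bad] %||% as.character(bad)
      stop_param(sprintf("constant ROI series (ROI %s): degenerate input", nm))
    }
    roi_series <- (roi_series - rowMeans(roi_series)) / sds
  }
  colMeans(roi_series)
}

#' Root mean square of successive differences
#'
#' `sqrt(mean((z[t+1] - z[t])^2))` with divisor `n - 1`: the order-sensitive
#' variability of a series. Zero iff the series is constant.
#'
#' @param series numeric vector, length >= 2.
#' @return A single non-negative number.
#' @export
rmssd <- function(series) {
  if (length(series) < 2L) stop_param("series needs at least 2 timepoints")
  sqrt(mean(diff(series)^2))
}

#' Time-series standard deviation (order-insensitive variability)
#'
#' Sample standard deviation (divisor `n - 1`) about the series mean;
#' invariant to permuting the timepoints — the defining contrast with
#' [rmssd()].
#'
#' @param series numeric vector, length >= 2.
#' @return A single non-negative number.
#' @export
series_sd <- function(series) {
  if (length(series) < 2L) stop_param("series needs at least 2 timepoints")
  sd(series)
}

#' Per-subject state-dynamics metrics
#'
#' Runs the full dynamics stage for one subject: grand z-normalisation,
#' pairwise state distances, NMDS embedding with stress-selected
#' dimensionality, transition velocities and their mean (muV); and, when an
#' ROI assignment is given, the ROI-mean z-series with its rMSSD and SD.
#' A time-constant input matrix is degenerate for the normalisation step;
#' it is handled by returning all metrics as exactly zero (no states ever
#' move and the mean series never varies).
#'
#' @param matrix_ conditioned voxels x timepoints [state_matrix()].
#' @param roi_assignment optional factor/vector of length `nrow(matrix_)`
#'   mapping each voxel to an ROI; enables the rMSSD/SD metrics.
#' @param fd_mean optional mean framewise displacement to carry along.
#' @param roi_label label stored on the result (e.g. `"DMN"`).
#' @param k_candidates,stress_threshold,restarts,seed,maxit embedding
#'   controls, see [embed_states()].
#' @return Object of class `dynamics_metrics`: one-row data frame with
#'   columns `roi_label`, `mu_v`, `rmssd`, `sd`, `roi_size`, `fd_mean`,
#'   `k`, `stress`, `seed`.
#' @export
state_dynamics <- function(matrix_, roi_assignment = NULL, fd_mean = NA_real_,
                           roi_label = "DMN", k_candidates = c(2L, 3L, 4L),
                           stress_threshold = 0.10, restarts = 8L, seed = 1L,
                           maxit = 200L) {
  vals <- unclass(matrix_)
  attributes(vals) <- attributes(vals)["dim"]
  n <- ncol(vals)
  time_constant <- all(vals == vals[, 1L])
  if (time_constant) {
    mu_v <- 0; k <- k_candidates[1L]; stress <- 0
    rms <- if (is.null(roi_assignment)) NA_real_ else 0
    ssd <- rms
  } else {
    zmat <- znormalize_matrix(matrix_)
    emb <- embed_states(state_distances(zmat), k_candidates = k_candidates,
                        stress_threshold = stress_threshold,
                        restarts = restarts, seed = seed, maxit = maxit)
    mu_v <- mean_transition_velocity(transition_velocities(emb), n = n)
    k <- emb$k; stress <- emb$stress
    rms <- NA_real_; ssd <- NA_real_
    if (!is.null(roi_assignment)) {
      roi_assignment <- as.factor(roi_assignment)
      if (length(roi_assignment) != nrow(vals)) {
        stop_param("`roi_assignment` must have one entry per voxel")
      }
      counts <- as.vector(table(roi_assignment))
      roi_means <- rowsum(vals, roi_assignment) / counts
      zbar <- roi_mean_zseries(roi_means)
      rms <- rmssd(zbar)
      ssd <- series_sd(zbar)
    }
  }
  out <- data.frame(roi_label = roi_label, mu_v = mu_v, rmssd = rms,
                    sd = ssd, roi_size = nrow(vals), fd_mean = fd_mean,
                    k = as.integer(k), stress = stress, seed = seed,
                    stringsAsFactors = FALSE)
  class(out) <- c("dynamics_metrics", "data.frame")
  out
}

#' @export
print.dynamics_metrics <- function(x, ...) {
  cat(sprintf(
    "<dynamics_metrics> %s: muV = %.3f, rMSSD = %s, SD = %s (k = %d, stress = %.3f)\n",
    x$roi_label, x$mu_v,
    ifelse(is.na(x$rmssd), "NA", sprintf("%.3f", x$rmssd)),
    ifelse(is.na(x$sd), "NA", sprintf("%.3f", x$sd)), x$k, x$stress))
  invisible(x)
}
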