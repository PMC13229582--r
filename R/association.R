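get_col <- function(table, col) {
  if (!col %in% names(table)) stop_param(sprintf("column `%s` not found", col))
  x <- as.numeric(table[[col]])
  if (any(is.na(x))) stop_param(sprintf("column `%s` has missing values", col))
  if (sd(x) == 0) stop_param(sprintf("zero-variance column: %s", col))
  x
}

#' Pearson correlation grid with BH-FDR adjustment
#'
#' Pearson correlation (two-sided test) for every metric-by-measure pair,
#' with Benjamini-Hochberg adjustment applied across all pairs of the
#' declared family. Within a family, adjusted p-values are monotone in the
#' raw p-values and never smaller than them.
#'
#' @param table one row per subject.
#' @param metrics,measures column names to cross.
#' @param family label of the multiple-testing family (one call = one
#'   family).
#' @return Object of class `association_table` (a data frame): columns
#'   `metric`, `measure`, `r`, `df`, `p_raw`, `p_fdr`, `n`, `family_id`.
#' @export
pearson_grid <- function(table, metrics, measures, family = "main") {
  n <- nrow(table)
  if (n < 4L) stop_param("need at least 4 subjects")
  pairs <- expand.grid(metric = metrics, measure = measures,
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- get_col(table, pairs$metric[i])
    y <- get_col(table, pairs$measure[i])
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    data.frame(metric = pairs$metric[i], measure = pairs$measure[i],
               r = unname(ct$estimate), df = unname(ct$parameter),
               p_raw = ct$p.value, n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- p.adjust(out$p_raw, method = "BH")
  out$family_id <- family
  out <- out[, c("metric", "measure", "r", "df", "p_raw", "p_fdr", "n",
                 "family_id")]
  class(out) <- c("association_table", "data.frame")
  out
}

#' @export
print.association_table <- function(x, digits = 3, ...) {
  cat(sprintf("<association_table> family '%s', %d tests, n = %d\n",
              x$family_id[1L], nrow(x), x$n[1L]))
  df <- as.data.frame(x)
  df$r <- round(df$r, digits)
  df$p_raw <- signif(df$p_raw, digits)
  df$p_fdr <- signif(df$p_fdr, digits)
  print(df[, c("metric", "measure", "r", "df", "p_raw", "p_fdr")],
        row.names = FALSE)
  invisible(x)
}

residualize_on <- function(y, xmat) {
  fit <- lm.fit(cbind(1, xmat), y)
  fit$residuals
}

#' Covariate-adjusted (partial) correlation
#'
#' Residualises both the metric and the measure on the covariates plus an
#' intercept and correlates the residuals; degrees of freedom are reduced
#' by the covariate count. A semi-partial variant (residualising the
#' metric only) is available behind `semi_partial`.
#'
#' @param table one row per subject.
#' @param metric,measure column names.
#' @param covariates character vector of covariate column names.
#' @param semi_partial residualise only the metric.
#' @return One-row data frame: `metric`, `measure`, `covariates`,
#'   `adjusted_r`, `df`, `adjusted_p`, `n`.
#' @export
adjusted_correlation <- function(table, metric, measure, covariates,
                                 semi_partial = FALSE) {
  x <- get_col(table, metric)
  y <- get_col(table, measure)
  if (length(covariates) == 0L) stop_param("no covariates supplied")
  cmat <- do.call(cbind, lapply(covariates, function(cv) get_col(table, cv)))
  colnames(cmat) <- covariates
  q <- ncol(cmat)
  n <- length(x)
  if (qr(cbind(1, cmat))$rank < q + 1L) {
    stop_param("collinear covariates: design matrix is rank deficient")
  }
  rx <- residualize_on(x, cmat)
  ry <- if (semi_partial) y - mean(y) else residualize_on(y, cmat)
  if (sd(rx) < 1e-12 * sd(x) || sd(ry) < 1e-12 * sd(y)) {
    stop_param("a variable is (numerically) explained by the covariates: adjusted correlation undefined")
  }
  r <- cor(rx, ry)
  df <- n - 2L - q
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tval), df)
  data.frame(metric = metric, measure = measure,
             covariates = paste(covariates, collapse = "+"),
             adjusted_r = r, df = df, adjusted_p = p, n = n,
             stringsAsFactors = FALSE)
}

#' Split a cohort into sub-batches and re-run the correlation grid
#'
#' Deterministic seeded random partition into `n_batches` near-equal
#' groups (or consecutive blocks with `mode = "order"`, mimicking
#' acquisition-order sub-batches), with the same grid and family
#' definitions applied per batch.
#'
#' @param table one row per subject.
#' @param metrics,measures passed to [pearson_grid()].
#' @param n_batches number of sub-batches (each must keep >= 10 subjects).
#' @param seed partition seed.
#' @param mode `"random"` or `"order"`.
#' @param family base family label (suffixed per batch).
#' @return List with `assignment` (integer vector), `tables` (list of
#'   sub-tables) and `grids` (list of [pearson_grid()] results).
#' @export
split_batches <- function(table, metrics, measures, n_batches = 2L,
                          seed = 1L, mode = c("random", "order"),
                          family = "batch") {
  n_batches <- check_count(n_batches, "n_batches", min = 2L)
  mode <- match.arg(mode)
  n <- nrow(table)
  if (floor(n / n_batches) < 10L) {
    stop_param("each batch must contain at least 10 subjects")
  }
  base <- rep(seq_len(n_batches), length.out = n)
  assignment <- if (mode == "random") {
    seed <- check_seed(seed)
    with_seed(seed, sample(base))
  } else {
    sort(base)
  }
  tables <- lapply(seq_len(n_batches), function(b) {
    table[assignment == b, , drop = FALSE]
  })
  grids <- lapply(seq_len(n_batches), function(b) {
    pearson_grid(tables[[b]], metrics, measures,
                 family = sprintf("%s%d", family, b))
  })
  list(assignment = assignment, tables = tables, grids = grids)
}

#' Descriptive statistics and inter-metric correlations
#'
#' Means, SDs, and the pairwise Pearson correlations (with raw p-values)
#' among a set of dynamics metrics — e.g. to report the basic effect sizes
#' of muV and rMSSD and their shared variance.
#'
#' @param table one row per subject.
#' @param metrics metric column names.
#' @return List with `descriptives` (data frame: metric, mean, sd, n) and
#'   `correlations` (an [pearson_grid()]-style table of the unique pairs).
#' @export
cross_metric_summary <- function(table, metrics) {
  cols <- lapply(metrics, function(m) get_col(table, m))
  names(cols) <- metrics
  desc <- data.frame(metric = metrics,
                     mean = vapply(cols, mean, numeric(1)),
                     sd = vapply(cols, sd, numeric(1)),
                     n = nrow(table), row.names = NULL,
                     stringsAsFactors = FALSE)
  pairs <- utils::combn(metrics, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    ct <- cor.test(cols[[pairs[1L, i]]], cols[[pairs[2L, i]]])
    data.frame(metric = pairs[1L, i], measure = pairs[2L, i],
               r = unname(ct$estimate), df = unname(ct$parameter),
               p_raw = ct$p.value, n = nrow(table),
               stringsAsFactors = FALSE)
  })
  cors <- do.call(rbind, res)
  cors$p_fdr <- p.adjust(cors$p_raw, method = "BH")
  cors$family_id <- "cross_metric"
  class(cors) <- c("association_table", "data.frame")
  list(descriptives = desc, correlations = cors)
}
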