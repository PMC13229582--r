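check_items <- function(items, n, lo, hi, name) {
  items <- suppressWarnings(as.numeric(items))
  if (length(items) != n) {
    stop_param(sprintf("%s needs exactly %d items, got %d", name, n,
                       length(items)))
  }
  if (any(is.na(items))) {
    stop_param(sprintf("%s has missing items (no imputation by default)",
                       name))
  }
  if (any(items != round(items)) || any(items < lo) || any(items > hi)) {
    stop_param(sprintf("%s items must be integers in %d-%d", name, lo, hi))
  }
  as.integer(items)
}

#' Score the CD-RISC (25 items, 0-4)
#'
#' Sum of the 25 item responses; totals range 0-100, higher = more
#' perceived ability to manage stress and adversity.
#'
#' @param items integer vector of 25 responses in 0-4.
#' @return The total score.
#' @examples
#' score_cdrisc(rep(4, 25))  # 100
#' @export
score_cdrisc <- function(items) {
  sum(check_items(items, 25L, 0L, 4L, "CD-RISC"))
}

#' Score the BRS (6 items, 1-5)
#'
#' Mean of the six items after recoding the reverse-keyed items (2, 4, 6)
#' as `6 - value`; means range 1-5, higher = more perceived ability to
#' bounce back. Set `reverse_keyed = FALSE` for responses already supplied
#' in scored orientation (as the synthetic generator produces).
#'
#' @param items integer vector of 6 responses in 1-5.
#' @param reverse_keyed recode items 2, 4, 6 before averaging.
#' @return The mean score.
#' @export
score_brs <- function(items, reverse_keyed = TRUE) {
  items <- check_items(items, 6L, 1L, 5L, "BRS")
  if (isTRUE(reverse_keyed)) {
    rev_idx <- c(2L, 4L, 6L)
    items[rev_idx] <- 6L - items[rev_idx]
  }
  mean(items)
}

#' RSA item-to-subscale map
#'
#' Reads the packaged item-to-subscale assignment (29 items over family
#' cohesion, social competence, social resources, personal strength and
#' future structured style). The packaged map is a configuration fixture —
#' users scoring real RSA data should supply the instrument's own mapping
#' via `path`.
#'
#' @param path optional CSV with columns `item` (1-29) and `subscale`.
#' @return Data frame with columns `item` and `subscale`.
#' @export
rsa_subscale_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rsa_subscales.csv", package = "statevel")
  }
  map <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item", "subscale") %in% names(map))) {
    stop_param("subscale map needs `item` and `subscale` columns")
  }
  if (!setequal(map$item, 1:29) || nrow(map) != 29L) {
    stop_param("subscale map must cover items 1-29 exactly once")
  }
  map[order(map$item), , drop = FALSE]
}

rsa_subscale_names <- c("family_cohesion", "social_competence",
                        "social_resources", "personal_strength",
                        "future_structured_style")

#' Score the RSA (29 items, 1-7) with its five subscales
#'
#' Subscale sums plus the grand total (range 29-203); higher = more
#' protective factors. The grand total always equals the sum of the five
#' subscale sums.
#'
#' @param items integer vector of 29 responses in 1-7.
#' @param subscale_map see [rsa_subscale_map()].
#' @return List with `total` and `subscales` (named numeric vector of the
#'   five subscale sums).
#' @export
score_rsa <- function(items, subscale_map = rsa_subscale_map()) {
  items <- check_items(items, 29L, 1L, 7L, "RSA")
  if (nrow(subscale_map) != 29L || !setequal(subscale_map$item, 1:29)) {
    stop_param("subscale map must cover items 1-29 exactly once")
  }
  if (!all(subscale_map$subscale %in% rsa_subscale_names)) {
    bad <- setdiff(unique(subscale_map$subscale), rsa_subscale_names)
    stop_param(sprintf("unknown RSA subscale(s): %s",
                       paste(bad, collapse = ", ")))
  }
  sums <- tapply(items[subscale_map$item], subscale_map$subscale, sum)
  subscales <- setNames(as.numeric(sums[rsa_subscale_names]),
                        rsa_subscale_names)
  if (any(is.na(subscales))) {
    stop_param("subscale map leaves an RSA subscale empty")
  }
  list(total = sum(items), subscales = subscales)
}

#' Intra- minus inter-personal composite score
#'
#' `1/2 (personal strength + future structured style) -
#'  1/3 (family cohesion + social competence + social resources)`:
#' the degree to which a respondent endorses intra-personal over
#' inter-personal protective factors.
#'
#' @param subscales named vector (or list) of the five RSA subscale sums.
#' @return The composite difference score.
#' @export
composite_intrainter <- function(subscales) {
  need <- rsa_subscale_names
  subscales <- unlist(subscales)[need]
  if (any(is.na(subscales))) {
    stop_param(sprintf("composite needs subscales: %s",
                       paste(need, collapse = ", ")))
  }
  0.5 * (subscales[["personal_strength"]] +
           subscales[["future_structured_style"]]) -
    (1 / 3) * (subscales[["family_cohesion"]] +
                 subscales[["social_competence"]] +
                 subscales[["social_resources"]])
}

#' Score all three instruments for a cohort
#'
#' Takes item-level responses, one row per subject with columns
#' `cdrisc_01..cdrisc_25`, `brs_01..brs_06` and `rsa_01..rsa_29`, and
#' returns totals, RSA subscale sums and the intra/inter composite.
#'
#' @param items data frame of item responses (a `subject` column is carried
#'   through if present).
#' @param brs_reverse_keyed passed to [score_brs()]; use `FALSE` for
#'   generator output, which is already in scored orientation.
#' @param subscale_map see [rsa_subscale_map()].
#' @return Data frame with columns `subject`, `cdrisc`, `brs`, `rsa`, the
#'   five `rsa_*` subscale sums and `composite`.
#' @export
score_scales <- function(items, brs_reverse_keyed = TRUE,
                         subscale_map = rsa_subscale_map()) {
  cd_cols <- sprintf("cdrisc_%02d", 1:25)
  brs_cols <- sprintf("brs_%02d", 1:6)
  rsa_cols <- sprintf("rsa_%02d", 1:29)
  missing_cols <- setdiff(c(cd_cols, brs_cols, rsa_cols), names(items))
  if (length(missing_cols) > 0L) {
    stop_param(sprintf("item table lacks columns: %s ...",
                       paste(head(missing_cols, 3L), collapse = ", ")))
  }
  n <- nrow(items)
  subject <- if ("subject" %in% names(items)) {
    as.character(items$subject)
  } else sprintf("sub%03d", seq_len(n))
  out <- data.frame(subject = subject, cdrisc = NA_real_, brs = NA_real_,
                    rsa = NA_real_, stringsAsFactors = FALSE)
  sub_mat <- matrix(NA_real_, n, 5L,
                    dimnames = list(NULL, paste0("rsa_", rsa_subscale_names)))
  for (i in seq_len(n)) {
    out$cdrisc[i] <- score_cdrisc(as.numeric(items[i, cd_cols]))
    out$brs[i] <- score_brs(as.numeric(items[i, brs_cols]),
                            reverse_keyed = brs_reverse_keyed)
    rsa <- score_rsa(as.numeric(items[i, rsa_cols]),
                     subscale_map = subscale_map)
    out$rsa[i] <- rsa$total
    sub_mat[i, ] <- rsa$subscales
  }
  out <- cbind(out, as.data.frame(sub_mat))
  out$composite <- 0.5 * (out$rsa_personal_strength +
                            out$rsa_future_structured_style) -
    (1 / 3) * (out$rsa_family_cohesion + out$rsa_social_competence +
                 out$rsa_social_resources)
  out
}

#' Principal component analysis of resilience measures
#'
#' PCA on the correlation matrix (measures standardised to mean 0, SD 1 —
#' required because the scales have incommensurate ranges). Loadings are
#' measure-component correlations (eigenvectors scaled by the square root
#' of their eigenvalues), so the squared loadings of a component sum to its
#' eigenvalue. Component signs are fixed deterministically: each component
#' is flipped, if needed, so that its largest-magnitude loading is
#' positive; an all-positive-loading component therefore always presents
#' as positive.
#'
#' @param score_table data frame of subject scores.
#' @param measures columns to analyse (default: all numeric columns).
#' @return Object of class `scale_pca`: `loadings` (measures x components),
#'   `eigenvalues`, `variance_explained` (proportions, summing to 1),
#'   `scores` (subjects x components, variance = eigenvalue),
#'   `sign_flips`, `center`, `scale`, `n`.
#' @export
pca_scales <- function(score_table, measures = NULL) {
  if (is.null(measures)) {
    measures <- names(score_table)[vapply(score_table, is.numeric,
                                          logical(1))]
  }
  miss <- setdiff(measures, names(score_table))
  if (length(miss) > 0L) {
    stop_param(sprintf("measures not in table: %s",
                       paste(miss, collapse = ", ")))
  }
  x <- as.matrix(score_table[, measures, drop = FALSE])
  if (nrow(x) < 3L) stop_param("PCA needs at least 3 subjects")
  if (ncol(x) < 2L) stop_param("PCA needs at least 2 measures")
  if (any(is.na(x))) stop_param("PCA input has missing values")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop_param(sprintf("constant measure: %s", measures[which(sds == 0)[1L]]))
  }
  ctr <- colMeans(x)
  xs <- scale(x, center = ctr, scale = sds)
  eig <- eigen(cor(x), symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  loadings <- vecs %*% diag(sqrt(vals), nrow = length(vals))
  scores <- xs %*% vecs
  sign_flips <- rep(1, length(vals))
  for (j in seq_along(vals)) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      sign_flips[j] <- -1
      loadings[, j] <- -loadings[, j]
      vecs[, j] <- -vecs[, j]
      scores[, j] <- -scores[, j]
    }
  }
  comp <- paste0("PC", seq_along(vals))
  dimnames(loadings) <- list(measures, comp)
  dimnames(scores) <- list(rownames(score_table), comp)
  structure(list(loadings = loadings, eigenvalues = vals,
                 variance_explained = vals / sum(vals), scores = scores,
                 rotation = vecs, sign_flips = sign_flips,
                 center = ctr, scale = sds, measures = measures,
                 n = nrow(x)),
            class = "scale_pca")
}

#' Orient a principal component by a loading contrast
#'
#' Components of a PCA are sign-indeterminate; for replicate-stable
#' analyses a component is oriented by a substantive contrast, e.g. the
#' "self-recovery amid low support" component is the one whose BRS loading
#' exceeds its RSA loading. Returns the component scores multiplied by
#' +/-1 so that `loading[positive] - loading[negative] > 0`.
#'
#' @param pca a [pca_scales()] result.
#' @param component component index or name (e.g. `2` or `"PC2"`).
#' @param positive,negative measure names defining the contrast.
#' @return Numeric vector of oriented component scores.
#' @export
orient_component <- function(pca, component, positive, negative) {
  stopifnot(inherits(pca, "scale_pca"))
  l <- pca$loadings[, component]
  if (!all(c(positive, negative) %in% names(l))) {
    stop_param("contrast measures not found among the PCA measures")
  }
  s <- sign(l[[positive]] - l[[negative]])
  if (s == 0) s <- 1
  pca$scores[, component] * s
}

#' @export
print.scale_pca <- function(x, digits = 3, ...) {
  cat(sprintf("<scale_pca> %d measures, n = %d\n", length(x$measures), x$n))
  tab <- rbind(round(x$loadings, digits),
               `% variance` = round(100 * x$variance_explained, 1))
  print(tab)
  invisible(x)
}
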