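#' Tukey HSD pairwise comparisons and significant-pair count
#'
#' Performs all pairwise group comparisons of one trait with the
#' Tukey-Kramer studentized-range procedure (exact Tukey HSD when group sizes
#' are equal) and counts the pairs significant at `alpha`.
#'
#' Two input modes share one code path:
#' * **raw mode** — `data` holds one row per olive; give `value` and `group`
#'   column names. Group means and the pooled error mean square are computed
#'   from the rows.
#' * **summary mode** — `data` holds one row per group with columns `mean`,
#'   `se`, `n` (and a group column); the per-group SD is reconstructed as
#'   `se * sqrt(n)` and pooled as `MSE = sum((n_i-1) s_i^2) / (N - G)`.
#'
#' In both modes the studentized-range statistic for groups *i, j* is
#' `q = |m_i - m_j| / sqrt(MSE/2 (1/n_i + 1/n_j))` with p-value from the
#' studentized-range distribution on `(G, N - G)` degrees of freedom.
#'
#' @param data Data frame (raw rows or group summaries).
#' @param value,group Column names (raw mode); in summary mode only `group`
#'   is used (default: first non-summary column).
#' @param alpha Familywise significance level in (0, 1).
#' @return An object of class `olive_tukey`: tidy pair table, symmetric
#'   p-value matrix, significant-pair count.
#' @examples
#' summ <- dplyr::filter(olive_trait_summary(), trait == "D_Volume")
#' tukey_pair_count(summ, group = "variety")$n_significant  # 6
#' @export
tukey_pair_count <- function(data, value = NULL, group = NULL, alpha = 0.05) {
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  summary_mode <- is.null(value) && all(c("mean", "se", "n") %in% names(data))
  if (summary_mode) {
    if (is.null(group)) {
      group <- setdiff(names(data), c("mean", "se", "n", "sd", "trait"))[1]
    }
    g <- as.character(data[[group]])
    means <- data$mean
    ns <- data$n
    sds <- data$se * sqrt(ns)
  } else {
    if (is.null(value) || is.null(group)) {
      stop_olive("raw mode needs `value` and `group` column names")
    }
    x <- data[[value]]
    g <- as.character(data[[group]])
    keep <- is.finite(x) & !is.na(g)
    x <- x[keep]; g <- g[keep]
    gs <- split(x, factor(g, levels = unique(g)))
    g <- names(gs)
    means <- vapply(gs, mean, 0)
    ns <- vapply(gs, length, 0L)
    sds <- vapply(gs, sd, 0)
  }
  means <- unname(means); ns <- unname(ns); sds <- unname(sds)
  G <- length(means)
  if (G < 2) stop_olive("need at least two groups")
  if (any(ns < 2)) stop_olive("every group needs n >= 2")
  N <- sum(ns)
  mse <- sum((ns - 1) * sds^2) / (N - G)
  pairs <- utils::combn(G, 2)
  pair_tbl <- purrr::map_dfr(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    se_ij <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se_ij
    p <- stats::ptukey(q, G, N - G, lower.tail = FALSE)
    tibble(group1 = g[i], group2 = g[j],
           diff = means[i] - means[j], se = se_ij, q = q, p = p)
  })
  pair_tbl$significant <- pair_tbl$p < alpha
  pm <- matrix(1, G, G, dimnames = list(g, g))
  pm[cbind(pair_tbl$group1, pair_tbl$group2)] <- pair_tbl$p
  pm[cbind(pair_tbl$group2, pair_tbl$group1)] <- pair_tbl$p
  structure(list(pairs = pair_tbl, p_matrix = pm,
                 n_significant = sum(pair_tbl$significant),
                 alpha = alpha, df = N - G, mse = mse,
                 mode = if (summary_mode) "summary" else "raw"),
            class = "olive_tukey")
}

#' @export
print.olive_tukey <- function(x, ...) {
  cat(sprintf("<olive_tukey> %d pairs, %d significant at alpha = %g (%s mode)\n",
              nrow(x$pairs), x$n_significant, x$alpha, x$mode))
  print(x$pairs)
  invisible(x)
}

#' @export
tidy.olive_tukey <- function(x, ...) x$pairs

#' @export
glance.olive_tukey <- function(x, ...) {
  tibble(n_significant = x$n_significant, alpha = x$alpha,
         df = x$df, mse = x$mse)
}

#' Tukey significant-pair counts across a battery of traits
#'
#' Applies [tukey_pair_count()] to every trait column (raw mode on a per-olive
#' table, or summary mode on a long summary table with columns `trait`,
#' `mean`, `se`, `n`).
#'
#' @param data Per-olive trait table or long per-trait group summary.
#' @param traits Trait columns to test (raw mode).
#' @param group Grouping column.
#' @param alpha Significance level.
#' @return Tibble with `trait` and `n_significant`.
#' @export
tukey_trait_battery <- function(data, traits = NULL, group = "variety",
                                alpha = 0.05) {
  if (all(c("trait", "mean", "se", "n") %in% names(data))) {
    purrr::map_dfr(unique(data$trait), function(tr) {
      res <- tukey_pair_count(data[data$trait == tr, ], group = group,
                              alpha = alpha)
      tibble(trait = tr, n_significant = res$n_significant)
    })
  } else {
    traits <- traits %||% intersect(OLIVE_TRAITS, names(data))
    purrr::map_dfr(traits, function(tr) {
      res <- tukey_pair_count(data, value = tr, group = group, alpha = alpha)
      tibble(trait = tr, n_significant = res$n_significant)
    })
  }
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations between numeric columns, with two-sided
#' p-values from the t transform on n - 2 degrees of freedom.
#'
#' @param data Data frame.
#' @param cols Columns to correlate (default: all numeric columns).
#' @return An `olive_pearson` object (matrices `r`, `p`, sample size `n`);
#'   `tidy()` gives the long pair table.
#' @export
pearson_matrix <- function(data, cols = NULL) {
  cols <- cols %||% names(data)[vapply(data, is.numeric, TRUE)]
  X <- as.matrix(data[cols])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 3) stop_olive("need at least 3 complete rows")
  zv <- apply(X, 2, sd) == 0
  if (any(zv)) {
    stop_olive("zero-variance column(s): ", paste(cols[zv], collapse = ", "))
  }
  r <- cor(X)
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  diag(p) <- 0
  structure(list(r = r, p = p, n = n), class = "olive_pearson")
}

#' @export
print.olive_pearson <- function(x, ...) {
  cat(sprintf("<olive_pearson> %d variables, n = %d\n", ncol(x$r), x$n))
  invisible(x)
}

#' @export
tidy.olive_pearson <- function(x, ...) {
  cn <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(var1 = cn[idx[, 1]], var2 = cn[idx[, 2]],
         r = x$r[idx], p = x$p[idx])
}

#' Mahalanobis outlier screen within groups
#'
#' Squared Mahalanobis distance of each olive to its own group centroid,
#' under the group covariance, with automatic fallback to the pooled
#' within-group covariance when a group is too small relative to the number
#' of predictors (or its covariance is singular). Rows are flagged above the
#' chi-square quantile with as many degrees of freedom as predictors.
#'
#' @param data Per-olive table.
#' @param traits Predictor columns (default: trait columns present).
#' @param group Grouping column.
#' @param quantile Chi-square flagging quantile (default 0.999).
#' @return `data` with `md2`, `md_cutoff`, `outlier` and `covariance_used`
#'   columns appended.
#' @export
mahalanobis_screen <- function(data, traits = NULL, group = "variety",
                               quantile = 0.999) {
  traits <- traits %||% intersect(OLIVE_TRAITS, names(data))
  X <- as.matrix(data[traits])
  g <- as.character(data[[group]])
  p <- ncol(X)
  cutoff <- stats::qchisq(quantile, df = p)
  # pooled within-group covariance as fallback
  groups <- unique(g)
  Ws <- lapply(groups, function(v) {
    Xv <- X[g == v, , drop = FALSE]
    (nrow(Xv) - 1) * cov(Xv)
  })
  pooled <- Reduce(`+`, Ws) / (nrow(X) - length(groups))
  pooled_ok <- is.finite(rcond_sym(pooled)) && rcond_sym(pooled) > 1e-12
  md2 <- numeric(nrow(X))
  used <- character(nrow(X))
  for (v in groups) {
    idx <- which(g == v)
    Xv <- X[idx, , drop = FALSE]
    S <- cov(Xv)
    use_group <- nrow(Xv) > p && rcond_sym(S) > 1e-12
    if (!use_group && !pooled_ok) {
      stop_olive("singular covariance for group ", v, " and no usable pooled fallback")
    }
    Suse <- if (use_group) S else pooled
    md2[idx] <- stats::mahalanobis(Xv, colMeans(Xv), Suse)
    used[idx] <- if (use_group) "group" else "pooled"
  }
  out <- as_tibble(data)
  out$md2 <- md2
  out$md_cutoff <- cutoff
  out$outlier <- md2 > cutoff
  out$covariance_used <- used
  out
}

rcond_sym <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  if (anyNA(ev) || max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}
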