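#' Canonical linear discriminant analysis
#'
#' Fits Fisher's canonical LDA by solving the generalized eigenproblem of the
#' between-group versus within-group scatter matrices. Canonical coefficients
#' are scaled so the pooled within-group covariance of the discriminant
#' scores is the identity; eigenvalues are those of `W^-1 B` (between scatter
#' over within scatter), sorted descending. Structure loadings are the pooled
#' within-group correlations between each predictor and each discriminant
#' function. At most `min(G - 1, p)` discriminant functions are retained.
#'
#' @param data Per-olive table.
#' @param predictors Predictor column names (default: all trait and note
#'   columns present). Categorical note predictors enter as their integer
#'   codes.
#' @param group Grouping column (default `"variety"`).
#' @param priors Class prior probabilities: `"equal"` (default) or
#'   `"proportional"`.
#' @param ridge Relative ridge added to a singular pooled covariance
#'   (`ridge * trace/p`), recorded in the fit when used.
#' @param allow_singleton Permit groups with a single row (used by
#'   leave-one-out refits; such groups contribute only to the between-group
#'   scatter).
#' @return An object of class `olive_lda` with eigenvalues, coefficients,
#'   structure loadings, group centroids and covariances in DF space, and the
#'   score table.
#' @export
fit_lda <- function(data, predictors = NULL, group = "variety",
                    priors = c("equal", "proportional"), ridge = 1e-8,
                    allow_singleton = FALSE) {
  priors <- match.arg(priors)
  predictors <- predictors %||%
    intersect(c(OLIVE_TRAITS, "E_Rugosity_index",
                VISUAL_CHARACTERISTICS, DERIVED_CHARACTERISTICS), names(data))
  y <- factor(data[[group]])
  if (nlevels(y) < 2) stop_olive("need at least two groups")
  if (!allow_singleton && any(table(y) < 2)) {
    stop_olive("every group needs at least two rows")
  }
  if (nrow(data) <= nlevels(y)) stop_olive("need more rows than groups")
  X <- as.matrix(data[predictors])
  storage.mode(X) <- "double"
  constant <- apply(X, 2, function(c0) sd(c0) == 0)
  if (any(constant)) {
    warning("dropping constant predictor(s): ",
            paste(predictors[constant], collapse = ", "), call. = FALSE)
    X <- X[, !constant, drop = FALSE]
    predictors <- predictors[!constant]
  }
  p <- ncol(X)
  G <- nlevels(y)
  n <- nrow(X)
  grand <- colMeans(X)
  # scatter matrices
  Wmat <- matrix(0, p, p)
  Bmat <- matrix(0, p, p)
  for (lev in levels(y)) {
    Xg <- X[y == lev, , drop = FALSE]
    mg <- colMeans(Xg)
    Xc <- sweep(Xg, 2, mg)
    Wmat <- Wmat + crossprod(Xc)
    Bmat <- Bmat + nrow(Xg) * tcrossprod(mg - grand)
  }
  Sw <- Wmat / (n - G)
  ridge_used <- 0
  C <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(C) || rcond_sym(Sw) < 1e-12) {
    ridge_used <- ridge * sum(diag(Sw)) / p
    C <- chol(Sw + diag(ridge_used, p))
  }
  Ci <- backsolve(C, diag(p))          # inverse of upper-triangular C
  M <- t(Ci) %*% (Bmat / (n - G)) %*% Ci
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  K <- min(G - 1, p)
  lambda <- pmax(eg$values[seq_len(K)], 0)
  A <- Ci %*% eg$vectors[, seq_len(K), drop = FALSE]
  rownames(A) <- predictors
  colnames(A) <- paste0("DF", seq_len(K))
  scores <- sweep(X, 2, grand) %*% A
  colnames(scores) <- colnames(A)
  centroids <- rowsum(scores, y) / as.numeric(table(y))
  group_cov <- lapply(levels(y), function(lev) {
    Xg <- scores[y == lev, , drop = FALSE]
    if (nrow(Xg) < 2) matrix(NA_real_, ncol(Xg), ncol(Xg)) else cov(Xg)
  })
  names(group_cov) <- levels(y)
  # structure loadings: pooled within-group predictor-DF correlations
  loadings <- sweep(Sw %*% A, 1, sqrt(diag(Sw)), `/`)
  prior_vec <- if (priors == "equal") rep(1 / G, G)
               else as.numeric(table(y)) / n
  names(prior_vec) <- levels(y)
  score_tbl <- bind_cols(
    if ("olive_id" %in% names(data)) tibble(olive_id = data$olive_id) else NULL,
    tibble(!!group := y), as_tibble(scores)
  )
  structure(
    list(eigenvalues = lambda, coefficients = A, loadings = loadings,
         centroids = centroids, group_cov = group_cov, priors = prior_vec,
         grand_mean = grand, predictors = predictors, group = group,
         levels = levels(y), scores = score_tbl, n = n,
         ridge_used = ridge_used),
    class = "olive_lda"
  )
}

#' @export
print.olive_lda <- function(x, ...) {
  cat(sprintf("<olive_lda> %d groups, %d predictors, %d discriminant functions\n",
              length(x$levels), length(x$predictors), length(x$eigenvalues)))
  cat("eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.olive_lda <- function(x, ...) {
  as_tibble(x$loadings, rownames = "predictor") |>
    tidyr::pivot_longer(-"predictor", names_to = "df", values_to = "loading")
}

#' @export
glance.olive_lda <- function(x, ...) {
  tibble(n = x$n, n_groups = length(x$levels),
         n_predictors = length(x$predictors),
         n_df = length(x$eigenvalues),
         ridge_used = x$ridge_used,
         prop_trace_df1 = x$eigenvalues[1] / sum(x$eigenvalues))
}

#' Discriminant-score scatter plot
#'
#' @param object An `olive_lda` fit.
#' @param dims Two discriminant functions to plot.
#' @param ... Unused.
#' @export
autoplot.olive_lda <- function(object, dims = c(1, 2), ...) {
  sc <- object$scores
  dfs <- paste0("DF", dims)
  ggplot2::ggplot(sc, ggplot2::aes(.data[[dfs[1]]], .data[[dfs[2]]],
                                   colour = .data[[object$group]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::stat_ellipse(level = 0.9, linewidth = 0.3) +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
}

#' Project new data onto the discriminant functions
#'
#' @param object An `olive_lda` fit.
#' @param newdata Table containing the fit's predictor columns.
#' @param ... Unused.
#' @return Matrix of discriminant scores.
#' @export
predict.olive_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$predictors])
  storage.mode(X) <- "double"
  sweep(X, 2, object$grand_mean) %*% object$coefficients
}

#' Classify discriminant scores to the nearest group centroid
#'
#' Assigns each score vector to the group with smallest Mahalanobis distance
#' to its centroid in DF space under the pooled within-group covariance
#' (identity by canonical scaling), adjusted by the log priors. Ties go to
#' the lowest group index.
#'
#' @param model An `olive_lda` fit.
#' @param scores Score matrix (default: the fit's own scores).
#' @param truth Optional true labels for a confusion matrix.
#' @return A list with `predicted` (factor) and, when `truth` is given,
#'   `confusion` (an [confusion_matrix()] object).
#' @export
classify <- function(model, scores = NULL, truth = NULL) {
  if (is.null(scores)) {
    scores <- as.matrix(model$scores[paste0("DF", seq_along(model$eigenvalues))])
    if (is.null(truth)) truth <- model$scores[[model$group]]
  }
  if (ncol(scores) != length(model$eigenvalues)) {
    stop_olive("score dimensionality does not match the model")
  }
  cent <- model$centroids
  d2 <- outer(rowSums(scores^2), rep(1, nrow(cent))) -
    2 * scores %*% t(cent) + outer(rep(1, nrow(scores)), rowSums(cent^2))
  d2 <- sweep(d2, 2, 2 * log(model$priors[rownames(cent)]))
  pred_idx <- apply(d2, 1, which.min)  # which.min: lowest index on ties
  predicted <- factor(model$levels[pred_idx], levels = model$levels)
  out <- list(predicted = predicted)
  if (!is.null(truth)) {
    out$confusion <- confusion_matrix(factor(truth, levels = model$levels),
                                      predicted)
  }
  out
}

#' Confusion matrix with per-class and overall accuracy
#'
#' @param truth,predicted Factors over the same levels (rows = truth,
#'   columns = predicted).
#' @return An `olive_confusion` object (counts, row percents, per-class and
#'   overall percent correct).
#' @export
confusion_matrix <- function(truth, predicted) {
  counts <- table(truth = truth, predicted = predicted)
  pct <- 100 * prop.table(counts + 0, 1)
  pct[is.nan(pct)] <- 0
  overall <- 100 * sum(diag(counts)) / sum(counts)
  structure(list(counts = unclass(counts), percent = unclass(pct),
                 per_class = diag(unclass(pct)), overall = overall),
            class = "olive_confusion")
}

#' @export
print.olive_confusion <- function(x, ...) {
  cat(sprintf("<olive_confusion> overall %.1f%% correct\n", x$overall))
  print(x$counts)
  invisible(x)
}

#' @export
tidy.olive_confusion <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)) |>
    dplyr::rename(count = "Freq")
}

#' @export
glance.olive_confusion <- function(x, ...) {
  tibble(overall_percent = x$overall, n = sum(x$counts))
}

#' Leave-one-out cross-validated classification
#'
#' Refits the LDA excluding each row in turn and classifies the held-out row.
#'
#' @inheritParams fit_lda
#' @return A list with `predicted`, `confusion` and `overall` percent.
#' @export
loocv <- function(data, predictors = NULL, group = "variety",
                  priors = "equal", ridge = 1e-8) {
  y <- factor(data[[group]])
  if (any(table(y) < 2)) stop_olive("leave-one-out needs at least two rows per group")
  n <- nrow(data)
  preds <- character(n)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(fit_lda(data[-i, , drop = FALSE], predictors,
                                    group, priors, ridge,
                                    allow_singleton = TRUE))
    sc <- predict(fit, data[i, , drop = FALSE])
    preds[i] <- as.character(classify(fit, sc)$predicted)
  }
  predicted <- factor(preds, levels = levels(y))
  cm <- confusion_matrix(y, predicted)
  list(predicted = predicted, confusion = cm, overall = cm$overall)
}

#' Bhattacharyya distance and coefficient between group score distributions
#'
#' For each pair of groups with DF-space moments (mu_1, Sigma_1) and
#' (mu_2, Sigma_2), the Bhattacharyya distance is
#' `D_B = 1/8 (mu_1-mu_2)' Sigma^-1 (mu_1-mu_2) +
#'   1/2 ln( det(Sigma) / sqrt(det(Sigma_1) det(Sigma_2)) )` with
#' `Sigma = (Sigma_1 + Sigma_2)/2`, and the coefficient is
#' `BhC = exp(-D_B)` (1 = identical distributions).
#'
#' @param scores An `olive_lda` fit, or a data frame with a group column plus
#'   numeric score columns.
#' @param group Group column name when `scores` is a data frame.
#' @param shrink Relative diagonal shrinkage applied to a group covariance
#'   that is singular or estimated from fewer rows than dimensions.
#' @return An `olive_overlap` object: tidy pair table and symmetric `D_B` /
#'   `BhC` matrices.
#' @export
bhattacharyya <- function(scores, group = "variety", shrink = 1e-6) {
  if (inherits(scores, "olive_lda")) {
    group <- scores$group
    scores <- scores$scores
  }
  num_cols <- names(scores)[vapply(scores, is.numeric, TRUE)]
  y <- factor(scores[[group]])
  S <- as.matrix(scores[num_cols])
  k <- ncol(S)
  moments <- lapply(levels(y), function(lev) {
    Xg <- S[y == lev, , drop = FALSE]
    Sg <- cov(Xg)
    if (nrow(Xg) <= k || rcond_sym(Sg) < 1e-10) {
      Sg <- Sg + diag(shrink * max(1, mean(diag(Sg))), k)
      message("covariance shrinkage applied to group ", lev)
    }
    list(mu = colMeans(Xg), S = Sg)
  })
  names(moments) <- levels(y)
  G <- nlevels(y)
  pairs <- utils::combn(G, 2)
  tbl <- purrr::map_dfr(seq_len(ncol(pairs)), function(c0) {
    a <- moments[[pairs[1, c0]]]; b <- moments[[pairs[2, c0]]]
    Sm <- (a$S + b$S) / 2
    dmu <- a$mu - b$mu
    term1 <- as.numeric(crossprod(dmu, solve(Sm, dmu))) / 8
    ld <- determinant(Sm, logarithm = TRUE)$modulus -
      0.5 * (determinant(a$S, logarithm = TRUE)$modulus +
               determinant(b$S, logarithm = TRUE)$modulus)
    db <- term1 + 0.5 * as.numeric(ld)
    tibble(group1 = levels(y)[pairs[1, c0]], group2 = levels(y)[pairs[2, c0]],
           D_B = db, BhC = exp(-db))
  })
  DBm <- matrix(0, G, G, dimnames = list(levels(y), levels(y)))
  BCm <- matrix(1, G, G, dimnames = list(levels(y), levels(y)))
  DBm[cbind(tbl$group1, tbl$group2)] <- tbl$D_B
  DBm[cbind(tbl$group2, tbl$group1)] <- tbl$D_B
  BCm[cbind(tbl$group1, tbl$group2)] <- tbl$BhC
  BCm[cbind(tbl$group2, tbl$group1)] <- tbl$BhC
  structure(list(pairs = tbl, D_B = DBm, BhC = BCm,
                 average_BhC = mean(tbl$BhC)),
            class = "olive_overlap")
}

#' @export
print.olive_overlap <- function(x, ...) {
  cat(sprintf("<olive_overlap> %d pairs, average BhC %.3f\n",
              nrow(x$pairs), x$average_BhC))
  print(x$pairs)
  invisible(x)
}

#' @export
tidy.olive_overlap <- function(x, ...) x$pairs

#' @export
glance.olive_overlap <- function(x, ...) {
  i <- which.max(x$pairs$BhC); j <- which.min(x$pairs$BhC)
  tibble(average_BhC = x$average_BhC,
         max_pair = paste(x$pairs$group1[i], x$pairs$group2[i], sep = "-"),
         max_BhC = x$pairs$BhC[i],
         min_pair = paste(x$pairs$group1[j], x$pairs$group2[j], sep = "-"),
         min_BhC = x$pairs$BhC[j])
}

#' Varietal-overlap heatmap
#'
#' @param object An `olive_overlap` result.
#' @param ... Unused.
#' @export
autoplot.olive_overlap <- function(object, ...) {
  long <- as_tibble(as.data.frame(as.table(object$BhC), stringsAsFactors = FALSE))
  names(long) <- c("group1", "group2", "BhC")
  ggplot2::ggplot(long, ggplot2::aes(.data$group1, .data$group2,
                                     fill = .data$BhC)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$BhC)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Potency-index ranking of predictors
#'
#' The potency index of a predictor sums, over discriminant functions, its
#' squared structure loading weighted by the function's eigenvalue — either
#' the raw eigenvalue (`mode = "raw"`) or the eigenvalue share
#' `lambda_j / sum(lambda)` (`mode = "relative"`). The two modes differ by a
#' constant factor, so ranks are identical.
#'
#' @param model An `olive_lda` fit.
#' @param mode `"raw"` or `"relative"` eigenvalue weighting.
#' @return An `olive_potency` tibble: `predictor`, `potency`, `rank`.
#' @export
potency_index <- function(model, mode = c("raw", "relative")) {
  mode <- match.arg(mode)
  w <- model$eigenvalues
  if (mode == "relative") w <- w / sum(w)
  pot <- as.numeric(model$loadings^2 %*% w)
  out <- tibble(predictor = rownames(model$loadings), potency = pot)
  out <- arrange(out, dplyr::desc(.data$potency))
  out$rank <- seq_len(nrow(out))
  class(out) <- c("olive_potency", class(out))
  out
}

#' Potency-index bar chart
#'
#' @param object An `olive_potency` ranking.
#' @param ... Unused.
#' @export
autoplot.olive_potency <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$potency,
                               stats::reorder(.data$predictor, .data$potency))) +
    ggplot2::geom_col(fill = "olivedrab") +
    ggplot2::labs(x = "potency index", y = NULL) +
    ggplot2::theme_minimal()
}
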