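#' Batch-stratified train/validation split
#'
#' Assigns each olive to the training or validation role so that (i) each
#' variety's training fraction is within one olive of the target ratio and
#' (ii) every (variety, year, farm) batch cell with at least two members
#' contributes at least one olive to training — mirroring a design where both
#' harvest years and all farms are represented during model fitting.
#'
#' @param data Per-olive table with the stratification columns.
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @param group Variety column.
#' @param strata Batch columns (default year and farm).
#' @return Tibble `olive_id`, variety/batch columns, and `role`
#'   (`"train"`/`"validation"`).
#' @export
stratified_split <- function(data, ratio = 0.7, seed = 1L, group = "variety",
                             strata = c("year", "farm")) {
  check_number(ratio, "ratio", lower = 1e-9, upper = 1 - 1e-9)
  missing_cols <- setdiff(c("olive_id", group, strata), names(data))
  if (length(missing_cols)) {
    stop_olive("missing stratification column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  if (any(table(data[[group]]) < 2)) {
    stop_olive("every variety needs at least two olives to split")
  }
  with_seed(seed, {
    cellkey <- interaction(data[strata], drop = TRUE)
    out <- purrr::map_dfr(split(data, data[[group]], drop = TRUE), function(dv) {
      n_v <- nrow(dv)
      target <- round(ratio * n_v)
      target <- min(max(target, 1L), n_v - 1L)
      cells <- split(seq_len(n_v), interaction(dv[strata], drop = TRUE))
      # initial allocation per cell: floor of the ratio, >= 1 when the cell
      # has >= 2 members
      alloc <- vapply(cells, function(idx) {
        k <- floor(ratio * length(idx))
        if (length(idx) >= 2) k <- max(k, 1L)
        min(k, length(idx))
      }, 0)
      # adjust to the per-variety target, respecting the cell constraints
      while (sum(alloc) < target) {
        room <- vapply(cells, length, 0L) - alloc
        cand <- which(room > 0)
        pick <- cand[which.max(room[cand])]
        alloc[pick] <- alloc[pick] + 1
      }
      while (sum(alloc) > target) {
        floor_k <- vapply(cells, function(idx) if (length(idx) >= 2) 1L else 0L, 0L)
        cand <- which(alloc > floor_k)
        pick <- cand[which.max(alloc[cand] - floor_k[cand])]
        alloc[pick] <- alloc[pick] - 1
      }
      role <- rep("validation", n_v)
      for (ci in seq_along(cells)) {
        idx <- cells[[ci]]
        take <- sample(idx, alloc[ci])
        role[take] <- "train"
      }
      bind_cols(dv[c("olive_id", group, strata)], tibble(role = role))
    })
    out
  })
}

#' Train a soft-margin linear SVM variety classifier
#'
#' One-vs-one multiclass linear support-vector machine (regularization
#' `cost`, default 1). Predictors are standardized by the *training-set*
#' mean and standard deviation only, so validation rows never influence the
#' fit.
#'
#' @param train Training table (rows with `role == "train"` of a
#'   [stratified_split()], joined back to the predictors).
#' @param predictors Predictor columns (default: trait and note columns
#'   present).
#' @param group Label column.
#' @param cost Soft-margin cost parameter C.
#' @return An `olive_svm` object with the fitted model, scaling parameters
#'   and training accuracy.
#' @export
train_linear_svm <- function(train, predictors = NULL, group = "variety",
                             cost = 1) {
  predictors <- predictors %||%
    intersect(c(OLIVE_TRAITS, "E_Rugosity_index",
                VISUAL_CHARACTERISTICS, DERIVED_CHARACTERISTICS), names(train))
  y <- factor(train[[group]])
  if (nlevels(droplevels(y)) < 2) stop_olive("training data has a single class")
  X <- as.matrix(train[predictors])
  storage.mode(X) <- "double"
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- scl > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], `/`)
  fit <- e1071::svm(Xs, droplevels(y), kernel = "linear", cost = cost,
                    scale = FALSE)
  train_pred <- stats::predict(fit, Xs)
  structure(
    list(fit = fit, predictors = predictors, keep = keep,
         center = ctr, scale = scl, levels = levels(droplevels(y)),
         group = group, cost = cost,
         train_accuracy = 100 * mean(train_pred == droplevels(y))),
    class = "olive_svm"
  )
}

#' @export
print.olive_svm <- function(x, ...) {
  cat(sprintf("<olive_svm> linear kernel, C = %g, %d predictors, train accuracy %.2f%%\n",
              x$cost, sum(x$keep), x$train_accuracy))
  invisible(x)
}

#' @export
predict.olive_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$predictors])
  storage.mode(X) <- "double"
  Xs <- sweep(sweep(X[, object$keep, drop = FALSE], 2,
                    object$center[object$keep]), 2,
              object$scale[object$keep], `/`)
  stats::predict(object$fit, Xs)
}

#' @export
glance.olive_svm <- function(x, ...) {
  tibble(cost = x$cost, n_predictors = sum(x$keep),
         n_support = x$fit$tot.nSV, train_accuracy = x$train_accuracy)
}

#' Evaluate an SVM on a held-out validation table
#'
#' @param model An `olive_svm`.
#' @param validation Validation table containing predictors and true labels.
#' @return A list with `predicted`, `confusion` and `overall` percent correct.
#' @export
evaluate_svm <- function(model, validation) {
  predicted <- predict(model, validation)
  truth <- factor(validation[[model$group]], levels = model$levels)
  predicted <- factor(predicted, levels = model$levels)
  cm <- confusion_matrix(truth, predicted)
  list(predicted = predicted, confusion = cm, overall = cm$overall)
}
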