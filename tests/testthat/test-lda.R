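make_blobs <- function(centers, n = 12, sd = 0.3, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(nrow(centers)), function(g) {
    tibble::tibble(variety = paste0("g", g),
                   x1 = rnorm(n, centers[g, 1], sd),
                   x2 = rnorm(n, centers[g, 2], sd))
  })
}

test_that("five groups with many predictors give four discriminant functions", {
  p <- build_default_profiles()
  tt <- sample_trait_table(p, seed = 3)
  vn <- sample_visual_notes(p, seed = 3)
  full <- dplyr::left_join(tt, vn[c("olive_id", "D_Apex", "D_Base", "D_Nipple",
                                    "E_Apex", "E_Base", "E_Mucron")],
                           by = "olive_id")
  preds <- setdiff(c(trait_names(), "D_Apex", "D_Base", "D_Nipple",
                     "E_Apex", "E_Base", "E_Mucron"), "E_Weight")  # 29
  fit <- fit_lda(full, preds)
  expect_length(fit$eigenvalues, 4)
  expect_equal(ncol(fit$coefficients), 4)
  expect_true(all(diff(fit$eigenvalues) <= 1e-9))
  # canonical scaling: pooled within-group covariance of scores = identity
  sc <- as.matrix(fit$scores[paste0("DF", 1:4)])
  y <- fit$scores$variety
  Wp <- Reduce(`+`, lapply(levels(y), function(l) {
    Xg <- sc[y == l, ]
    crossprod(sweep(Xg, 2, colMeans(Xg)))
  })) / (nrow(sc) - 5)
  expect_equal(unname(Wp), diag(4), tolerance = 1e-8)
})

test_that("eigenvalues match a dense generalized-eigensolver oracle", {
  d <- make_blobs(matrix(c(0, 0, 2, 0, 1, 2), 3, 2, byrow = TRUE), seed = 7)
  fit <- fit_lda(d, c("x1", "x2"))
  expect_equal(fit$eigenvalues, brute_lda_eigen(d, c("x1", "x2"), "variety"),
               tolerance = 1e-8)
})

test_that("classification follows nearest centroid with low-index tie-break", {
  d <- make_blobs(matrix(c(0, 0, 10, 0), 2, 2, byrow = TRUE), sd = 0.5, seed = 3)
  fit <- fit_lda(d, c("x1", "x2"))
  cls <- classify(fit)
  expect_equal(cls$confusion$overall, 100)
  expect_true(all(cls$confusion$counts == diag(c(12, 12))))
  # a point exactly at a centroid goes to that group
  sc <- matrix(fit$centroids["g2", ], 1)
  expect_equal(as.character(classify(fit, sc)$predicted), "g2")
  # equidistant point -> lowest group index
  mid <- matrix(colMeans(fit$centroids), 1)
  expect_equal(as.character(classify(fit, mid)$predicted), "g1")
  expect_error(classify(fit, matrix(0, 1, 5)), "dimensionality")
})

test_that("well-separated groups achieve 100% leave-one-out accuracy", {
  d <- make_blobs(matrix(c(0, 0, 10, 0), 2, 2, byrow = TRUE), sd = 0.5, seed = 4)
  cv <- loocv(d, c("x1", "x2"))
  expect_equal(cv$overall, 100)
})

test_that("leave-one-out matches an independent per-fold reference", {
  # n = 6 toy (3 groups x 2 rows): every fold refit checked against MASS::lda
  set.seed(12)
  d <- tibble::tibble(
    variety = rep(c("a", "b", "c"), each = 2),
    x1 = c(0, 0.4, 4, 4.4, 0.2, 0.5),
    x2 = c(0, 0.3, 0.1, 0.4, 4, 4.5)
  )
  ours <- loocv(d, c("x1", "x2"))
  ref <- vapply(seq_len(6), function(i) {
    m <- MASS::lda(d[-i, c("x1", "x2")], grouping = d$variety[-i],
                   prior = rep(1 / 3, 3))
    as.character(stats::predict(m, d[i, c("x1", "x2")])$class)
  }, "")
  expect_equal(as.character(ours$predicted), ref)
  # one row per group -> error
  d1 <- d[c(1, 3, 5), ]
  expect_error(loocv(d1, c("x1", "x2")), "two rows per group")
})

test_that("constant predictors are dropped with a warning", {
  d <- make_blobs(matrix(c(0, 0, 3, 0), 2, 2, byrow = TRUE), seed = 5)
  d$flat <- 1
  expect_warning(fit <- fit_lda(d, c("x1", "x2", "flat")), "constant")
  expect_equal(fit$predictors, c("x1", "x2"))
})

test_that("classification is invariant to affine rescaling of predictors", {
  d <- make_blobs(matrix(c(0, 0, 2, 1, 0, 2), 3, 2, byrow = TRUE), seed = 6)
  f1 <- fit_lda(d, c("x1", "x2"))
  d2 <- dplyr::mutate(d, x1 = 100 * x1 - 7, x2 = 0.01 * x2 + 3)
  f2 <- fit_lda(d2, c("x1", "x2"))
  expect_equal(as.character(classify(f1)$predicted),
               as.character(classify(f2)$predicted))
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-8)
})

test_that("Bhattacharyya distance matches 1-D closed forms", {
  # exact sample moments via standardization
  std <- function(x, mu, s) mu + s * (x - mean(x)) / sd(x)
  set.seed(21)
  a <- std(rnorm(60), 0, 1); b <- std(rnorm(60), 2, 1)
  d <- tibble::tibble(variety = rep(c("a", "b"), each = 60), DF1 = c(a, b))
  ov <- bhattacharyya(d)
  expect_equal(ov$pairs$D_B, 0.5, tolerance = 1e-10)
  expect_equal(ov$pairs$BhC, exp(-0.5), tolerance = 1e-10)
  # equal means, variances 1 and 4
  b2 <- std(rnorm(60), 0, 2)
  d2 <- tibble::tibble(variety = rep(c("a", "b"), each = 60), DF1 = c(a, b2))
  ov2 <- bhattacharyya(d2)
  expect_equal(ov2$pairs$D_B, 0.5 * log(2.5 / 2), tolerance = 1e-10)
  # identical moments -> D_B = 0, BhC = 1
  d3 <- tibble::tibble(variety = rep(c("a", "b"), each = 60), DF1 = c(a, a))
  ov3 <- bhattacharyya(d3)
  expect_equal(ov3$pairs$D_B, 0, tolerance = 1e-12)
  expect_equal(ov3$pairs$BhC, 1, tolerance = 1e-12)
})

test_that("overlap invariants hold on random Gaussian groups", {
  set.seed(77)
  for (i in 1:500) {
    k <- sample(1:3, 1)
    n <- sample(8:20, 1)
    d <- purrr::map_dfr(c("a", "b", "c"), function(g) {
      mu <- rnorm(k, sd = 2)
      X <- matrix(rnorm(n * k), n, k)
      out <- as.data.frame(sweep(X, 2, mu, `+`))
      names(out) <- paste0("DF", seq_len(k))
      dplyr::bind_cols(tibble::tibble(variety = rep(g, n)), out)
    })
    ov <- suppressMessages(bhattacharyya(d))
    expect_true(all(ov$pairs$D_B >= -1e-10))
    expect_true(all(ov$pairs$BhC > 0 & ov$pairs$BhC <= 1 + 1e-10))
    expect_equal(ov$D_B, t(ov$D_B))
    expect_equal(ov$BhC, t(ov$BhC))
  }
})

test_that("BhC strictly decreases as centroid separation grows", {
  set.seed(31)
  base <- rnorm(40)
  vals <- vapply(c(0.5, 1, 2, 4), function(sep) {
    d <- tibble::tibble(variety = rep(c("a", "b"), each = 40),
                        DF1 = c(base, base + sep))
    bhattacharyya(d)$pairs$BhC
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("potency index weights squared loadings by eigenvalues", {
  model <- structure(list(
    eigenvalues = c(2, 1, 0.5, 0.1),
    loadings = matrix(c(1, 0, 0, 0,
                        0, 0, 0, 0),
                      2, 4, byrow = TRUE,
                      dimnames = list(c("p1", "p2"), paste0("DF", 1:4)))
  ), class = "olive_lda")
  raw <- potency_index(model, mode = "raw")
  expect_equal(raw$potency[raw$predictor == "p1"], 2)
  expect_equal(raw$potency[raw$predictor == "p2"], 0)
  expect_equal(raw$rank[raw$predictor == "p2"], 2)  # all-zero loadings rank last
  rel <- potency_index(model, mode = "relative")
  expect_equal(rel$potency[rel$predictor == "p1"], 2 / 3.6, tolerance = 1e-12)
  # ranks agree across modes on fitted models
  d <- make_blobs(matrix(c(0, 0, 2, 0, 0, 2), 3, 2, byrow = TRUE), seed = 8)
  d$x3 <- rnorm(nrow(d))
  fit <- fit_lda(d, c("x1", "x2", "x3"))
  expect_equal(potency_index(fit, "raw")$predictor,
               potency_index(fit, "relative")$predictor)
})

test_that("tidy/glance/autoplot methods return well-formed objects", {
  d <- make_blobs(matrix(c(0, 0, 2, 0, 0, 2), 3, 2, byrow = TRUE), seed = 9)
  fit <- fit_lda(d, c("x1", "x2"))
  td <- tidy(fit)
  expect_true(all(c("predictor", "df", "loading") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_groups, 3)
  ov <- bhattacharyya(fit)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(ov), "ggplot")
  expect_s3_class(autoplot(potency_index(fit)), "ggplot")
})
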