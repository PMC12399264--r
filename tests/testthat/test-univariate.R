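test_that("Tukey pair counts: summary mode reproduces the published counts", {
  ts <- olive_trait_summary()
  dv <- tukey_pair_count(dplyr::filter(ts, trait == "D_Volume"), group = "variety")
  expect_equal(dv$n_significant, 6)
  ev <- tukey_pair_count(dplyr::filter(ts, trait == "E_Volume"), group = "variety")
  expect_equal(ev$n_significant, 8)
  # p-value matrix is symmetric with unit diagonal
  expect_equal(dv$p_matrix, t(dv$p_matrix))
  expect_equal(unname(diag(dv$p_matrix)), rep(1, 5))
})

test_that("summary mode equals raw mode on the same data", {
  set.seed(42)
  raw <- tibble::tibble(
    g = rep(c("a", "b", "c"), times = c(12, 9, 15)),
    y = rnorm(36, rep(c(0, 0.8, 0.3), times = c(12, 9, 15)))
  )
  r1 <- tukey_pair_count(raw, value = "y", group = "g")
  summ <- dplyr::summarise(dplyr::group_by(raw, g),
                           mean = mean(y), se = sd(y) / sqrt(dplyr::n()),
                           n = dplyr::n())
  r2 <- tukey_pair_count(summ, group = "g")
  expect_equal(r1$pairs$p, r2$pairs$p, tolerance = 1e-12)
  expect_equal(r1$n_significant, r2$n_significant)
  # and matches stats::TukeyHSD on balanced data
  set.seed(43)
  bal <- tibble::tibble(g = rep(c("a", "b", "c"), each = 10),
                        y = rnorm(30, rep(c(0, 1, 0.4), each = 10)))
  ours <- tukey_pair_count(bal, value = "y", group = "g")
  ref <- stats::TukeyHSD(stats::aov(y ~ g, data = bal))$g[, "p adj"]
  expect_equal(sort(ours$pairs$p), sort(unname(ref)), tolerance = 1e-6)
})

test_that("identical group means give zero significant pairs", {
  d <- tibble::tibble(g = c("a", "b", "c"), mean = 5, se = 0.3, n = 10)
  expect_equal(tukey_pair_count(d, group = "g")$n_significant, 0)
  expect_error(tukey_pair_count(d, group = "g", alpha = 2), "alpha")
  d2 <- tibble::tibble(g = c("a", "b"), mean = c(1, 2), se = 0.1, n = c(1, 5))
  expect_error(tukey_pair_count(d2, group = "g"), "n >= 2")
})

test_that("Pearson matrix matches hand computation and bounds", {
  d <- tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 4))
  pm <- pearson_matrix(d)
  expect_equal(pm$r["x", "y"], 3 / sqrt(2 * 4.6667), tolerance = 1e-4)
  expect_equal(unname(diag(pm$r)), c(1, 1))
  expect_equal(pm$r["x", "y"], unname(cor.test(d$x, d$y)$estimate),
               tolerance = 1e-12)
  expect_equal(pm$p["x", "y"], cor.test(d$x, d$y)$p.value, tolerance = 1e-12)
  set.seed(8)
  big <- tibble::tibble(a = rnorm(10000), b = rnorm(10000))
  expect_lt(abs(pearson_matrix(big)$r["a", "b"]), 0.05)
  expect_error(pearson_matrix(tibble::tibble(a = rep(1, 5), b = 1:5)),
               "zero-variance")
})

test_that("Mahalanobis screen flags at the chi-square rate and handles fallback", {
  set.seed(9)
  n <- 100000
  d <- tibble::tibble(variety = "v",
                      D_Volume = rnorm(n), D_Weight = rnorm(n),
                      E_Volume = rnorm(n))
  out <- mahalanobis_screen(d, traits = c("D_Volume", "D_Weight", "E_Volume"))
  expect_equal(mean(out$outlier), 0.001, tolerance = 0.35)
  # identity covariance: distances equal squared Euclidean to the centroid
  X <- as.matrix(d[2:4])
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(out$md2, unname(stats::mahalanobis(X, colMeans(X), cov(X))))
  expect_lt(max(abs(out$md2 - rowSums(Xc^2))), 0.05 * max(out$md2))
  # centroid row is never flagged
  ctr <- tibble::tibble(variety = "v",
                        D_Volume = mean(d$D_Volume), D_Weight = mean(d$D_Weight),
                        E_Volume = mean(d$E_Volume))
  both <- mahalanobis_screen(dplyr::bind_rows(d, ctr),
                             traits = c("D_Volume", "D_Weight", "E_Volume"))
  expect_false(both$outlier[nrow(both)])
  expect_lt(both$md2[nrow(both)], 1e-3)
  # small group relative to dimensionality -> pooled fallback
  set.seed(10)
  small <- tibble::tibble(variety = rep(c("a", "b"), c(40, 5)))
  for (j in 1:8) small[[paste0("t", j)]] <- rnorm(45)
  res <- mahalanobis_screen(small, traits = paste0("t", 1:8))
  expect_true(all(res$covariance_used[small$variety == "b"] == "pooled"))
  expect_true(all(res$covariance_used[small$variety == "a"] == "group"))
})

test_that("trait battery mirrors the per-trait pair counts", {
  ts <- olive_trait_summary()
  bat <- tukey_trait_battery(ts)
  expect_equal(nrow(bat), 24)
  expect_equal(bat$n_significant[bat$trait == "D_Volume"], 6)
  expect_equal(bat$n_significant[bat$trait == "E_Volume"], 8)
  expect_equal(bat$n_significant[bat$trait == "E_Position_of_MTA"], 0)
})
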