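# independent oracles and small fixture builders used across tests

# exhaustive between-class-variance maximizer (Otsu oracle)
brute_otsu <- function(counts, levels = seq_along(counts) - 1) {
  n <- sum(counts)
  best <- -Inf; best_t <- levels[1]
  for (i in seq_along(levels)) {
    w0 <- sum(counts[seq_len(i)]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[seq_len(i)] * levels[seq_len(i)]) / sum(counts[seq_len(i)])
    hi <- seq(i + 1, length(levels))
    mu1 <- sum(counts[hi] * levels[hi]) / sum(counts[hi])
    v <- w0 * w1 * (mu1 - mu0)^2
    if (v > best + 1e-12) { best <- v; best_t <- levels[i] }
  }
  best_t
}

# dense generalized-eigenproblem oracle for canonical LDA
brute_lda_eigen <- function(data, predictors, group) {
  X <- as.matrix(data[predictors])
  y <- factor(data[[group]])
  p <- ncol(X); n <- nrow(X); G <- nlevels(y)
  grand <- colMeans(X)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in levels(y)) {
    Xg <- X[y == lev, , drop = FALSE]
    mg <- colMeans(Xg)
    W <- W + crossprod(sweep(Xg, 2, mg))
    B <- B + nrow(Xg) * tcrossprod(mg - grand)
  }
  ev <- eigen(solve(W / (n - G)) %*% (B / (n - G)))$values
  sort(Re(ev), decreasing = TRUE)[seq_len(min(G - 1, p))]
}

# simplified SMO solver for the 2-class soft-margin linear SVM dual
# (John Platt's algorithm without heuristics; adequate for <= 20 points)
smo_svm <- function(X, y, C = 1, tol = 1e-6, max_passes = 200) {
  n <- nrow(X)
  K <- X %*% t(X)
  alpha <- rep(0, n); b <- 0
  f <- function(i) sum(alpha * y * K[, i]) + b
  passes <- 0
  while (passes < max_passes) {
    changed <- 0
    for (i in 1:n) {
      Ei <- f(i) - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) || (y[i] * Ei > tol && alpha[i] > 0)) {
        for (j in seq_len(n)[-i]) {
        Ej <- f(j) - y[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(H, max(L, aj))
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] - y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] - y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
        changed <- changed + 1
        break
        }
      }
    }
    passes <- if (changed == 0) passes + 1 else 0
  }
  w <- as.numeric(t(alpha * y) %*% X)
  list(alpha = alpha, w = w, b = b,
       decision = function(Z) as.numeric(Z %*% w + b))
}

# one-vs-one multiclass prediction from pairwise SMO machines
smo_ovo_predict <- function(X, y, Xnew, C = 1) {
  levs <- levels(factor(y))
  votes <- matrix(0, nrow(Xnew), length(levs), dimnames = list(NULL, levs))
  for (a in seq_len(length(levs) - 1)) for (b0 in seq(a + 1, length(levs))) {
    sel <- y %in% c(levs[a], levs[b0])
    yy <- ifelse(y[sel] == levs[a], 1, -1)
    m <- smo_svm(X[sel, , drop = FALSE], yy, C)
    d <- m$decision(Xnew)
    votes[, levs[a]] <- votes[, levs[a]] + (d >= 0)
    votes[, levs[b0]] <- votes[, levs[b0]] + (d < 0)
  }
  levs[apply(votes, 1, which.max)]
}

# digitized solids on centered grids
make_sphere <- function(r, n = 2 * r + 16) {
  g <- seq_len(n) - (n + 1) / 2
  outer(outer(g^2, g^2, `+`), g^2, `+`) <= r^2
}

make_ellipsoid <- function(a, b, c0, n = 2 * max(a, b, c0) + 16) {
  g <- seq_len(n) - (n + 1) / 2
  outer(outer(g^2 / a^2, g^2 / b^2, `+`), g^2 / c0^2, `+`) <= 1
}

# closed-form prolate spheroid surface area (semi-axes a = b < c)
spheroid_area <- function(a, c0) {
  e <- sqrt(1 - a^2 / c0^2)
  2 * pi * a^2 * (1 + (c0 / (a * e)) * asin(e))
}

# rotate a mask about its centroid (nearest-neighbour, fixed output canvas)
rotate_mask <- function(mask, R, out_dim = dim(mask)) {
  d_in <- dim(mask)
  ctr_in <- (d_in + 1) / 2
  ctr_out <- (out_dim + 1) / 2
  idx <- arrayInd(seq_len(prod(out_dim)), out_dim)
  U <- sweep(idx, 2, ctr_out)
  S <- U %*% R  # inverse rotation of the output grid (R orthonormal)
  src <- sweep(S, 2, ctr_in, `+`)
  i <- round(src[, 1]); j <- round(src[, 2]); k <- round(src[, 3])
  ok <- i >= 1 & i <= d_in[1] & j >= 1 & j <= d_in[2] & k >= 1 & k <= d_in[3]
  out <- array(FALSE, out_dim)
  out[ok] <- mask[cbind(i[ok], j[ok], k[ok])]
  out
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# small standard phantom reused by several tests (cached per session)
default_test_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- phantom_spec(mta_offset = 10, groove_count = 4L,
                        lenticel_count = 20L, voxel_size = 250, seed = 3)
      cache <<- c(generate_drupe_phantom(sp), list(spec = sp))
    }
    cache
  }
})
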