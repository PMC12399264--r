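# --- low-level voxel utilities ------------------------------------------------

# separable Gaussian smoothing of a 3-D array (kernel truncated at 3 sigma);
# borders are zero-padded, adequate for objects away from the grid border
gaussian_smooth3 <- function(arr, sigma = 1.5) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(arr)
  conv_dim1 <- function(a) {
    n <- dim(a)[1]
    K <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[off + r + 1]
    }
    array(K %*% matrix(a, n), dim(a))
  }
  a <- conv_dim1(arr)
  a <- aperm(conv_dim1(aperm(a, c(2, 1, 3))), c(2, 1, 3))
  aperm(conv_dim1(aperm(a, c(3, 2, 1))), c(3, 2, 1))
}

erode6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, dd, s) {
    res <- array(FALSE, d)
    src <- lapply(seq_along(d), function(i) seq_len(d[i]))
    dst <- src
    if (s > 0) { dst[[dd]] <- seq(1 + s, d[dd]); src[[dd]] <- seq(1, d[dd] - s) }
    else       { dst[[dd]] <- seq(1, d[dd] + s); src[[dd]] <- seq(1 - s, d[dd]) }
    res[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    res
  }
  for (dd in 1:3) for (s in c(-1, 1)) out <- out & shift(mask, dd, s)
  out
}

boundary_shell <- function(mask) mask & !erode6(mask)

# triangulated isosurface area and mesh-enclosed volume of a mask, in voxel
# units: marching tetrahedra at the 0.5 level of the Gaussian-smoothed
# indicator field
mask_isosurface <- function(mask, sigma = 0.8) {
  f <- gaussian_smooth3(array(as.double(mask), dim(mask)), sigma)
  res <- .march_tet(f, dim(mask), 0.5)
  list(area = res[1], volume = res[2])
}

# convex-hull surface area of a voxel point cloud (Cauchy projection formula:
# 4 x mean projected hull area over quasi-uniform directions)
convex_hull_area <- function(coords, n_dir = 196) {
  i <- seq_len(n_dir)
  phi <- (1 + sqrt(5)) / 2
  zc <- 1 - (2 * i - 1) / n_dir
  th <- 2 * pi * i / phi
  dirs <- cbind(sqrt(1 - zc^2) * cos(th), sqrt(1 - zc^2) * sin(th), zc)
  areas <- vapply(seq_len(n_dir), function(j) {
    u <- dirs[j, ]
    a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v <- a - sum(a * u) * u; v <- v / sqrt(sum(v^2))
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    P <- coords %*% cbind(v, w)
    h <- grDevices::chull(P)
    p <- P[h, , drop = FALSE]
    n <- nrow(p)
    if (n < 3) return(0)
    nxt <- c(2:n, 1)
    abs(sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])) / 2
  }, 0)
  4 * mean(areas)
}

mask_coords <- function(mask) arrayInd(which(mask), dim(mask))

slice_area_profile <- function(mask) apply(mask, 3, sum)

# --- per-solid metrics --------------------------------------------------------

#' Volume, surface and shape metrics of an aligned solid
#'
#' Computes the scalar size/shape traits of one segmented compartment: voxel
#' volume, triangulated isosurface area, Wadell sphericity
#' (`pi^(1/3) (6V)^(2/3) / A`), length along +z, maximum transverse Feret
#' extent, the two principal transverse extents (the smaller reported as
#' `height`), elongation `L/W` and transverse flatness.
#'
#' @param mask Logical 3-D array aligned so the long axis lies on +z.
#' @param voxel_size Voxel edge length in micrometres.
#' @param smooth_sigma Gaussian pre-smoothing (voxels) for the isosurface.
#' @return A one-row tibble: `volume` (mm^3), `surface_area` (mm^2),
#'   `sphericity`, `L`, `W`, `height` (mm), `L_W`, `flatness`.
#' @export
solid_metrics <- function(mask, voxel_size, smooth_sigma = 0.8) {
  if (!any(mask)) stop_olive("empty mask")
  mm <- voxel_size / 1000
  nvox <- sum(mask)
  volume <- nvox * mm^3
  iso <- mask_isosurface(mask, smooth_sigma)
  area <- iso$area * mm^2
  sph <- pi^(1 / 3) * (6 * volume)^(2 / 3) / area
  co <- mask_coords(mask)
  L <- (diff(range(co[, 3])) + 1) * mm
  # max transverse Feret extent over z-slices, from per-slice hull points
  W_vox <- 0
  for (k in unique(co[, 3])) {
    p <- co[co[, 3] == k, 1:2, drop = FALSE]
    if (nrow(p) < 2) next
    h <- p[grDevices::chull(p), , drop = FALSE]
    dmax <- max(dist(h))
    if (dmax > W_vox) W_vox <- dmax
  }
  W <- (W_vox + 1) * mm
  # principal transverse extents of the xy-projection
  xy <- unique(co[, 1:2, drop = FALSE])
  ext <- if (nrow(xy) > 2) {
    ev <- eigen(cov(xy), symmetric = TRUE)$vectors
    pr <- xy %*% ev
    (apply(pr, 2, function(x) diff(range(x))) + 1) * mm
  } else c(mm, mm)
  tibble(volume = volume, surface_area = area, sphericity = sph,
         L = L, W = W, height = min(ext), L_W = L / W,
         flatness = min(ext) / max(ext))
}

#' Position of the maximum transverse area
#'
#' Locates the slice of maximum cross-sectional area (after smoothing the
#' area profile with a 3-slice moving average; ties resolved by the plateau
#' centroid) and reports its position as a signed percentage of the length,
#' positive toward the apex (+z).
#'
#' @inheritParams solid_metrics
#' @return Signed percentage of L in `[-50, 50]`.
#' @export
position_of_mta <- function(mask) {
  if (!any(mask)) stop_olive("empty mask")
  a <- slice_area_profile(mask)
  nz <- which(a > 0)
  a <- a[nz]
  sm <- as.numeric(stats::filter(a, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- a[is.na(sm)]
  peak <- mean(which(sm == max(sm)))
  L <- length(a)
  mid <- (1 + L) / 2
  100 * (peak - mid) / L
}

#' Bilateral-asymmetry coefficient
#'
#' Sweeps candidate mirror planes containing the z-axis (through the xy
#' centroid) and returns the maximum Dice overlap between the mask and its
#' reflection. 1 means perfectly bilaterally symmetric.
#'
#' @inheritParams solid_metrics
#' @param step_deg Azimuth step of the mirror-plane sweep in degrees.
#' @return Coefficient in `[0, 1]`.
#' @export
asymmetry_coefficient <- function(mask, step_deg = 1) {
  if (!any(mask)) stop_olive("empty mask")
  co <- mask_coords(mask)
  n <- nrow(co)
  cx <- mean(co[, 1]); cy <- mean(co[, 2])
  x <- co[, 1] - cx; y <- co[, 2] - cy
  d <- dim(mask)
  best <- 0
  for (phi in seq(0, 180 - step_deg, by = step_deg) * pi / 180) {
    nx <- -sin(phi); ny <- cos(phi)  # normal of the plane at azimuth phi
    proj <- 2 * (x * nx + y * ny)
    xi <- as.integer(round(x - proj * nx + cx))
    yi <- as.integer(round(y - proj * ny + cy))
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2]
    inter <- sum(mask[cbind(xi[ok], yi[ok], co[ok, 3])])
    dice <- 2 * inter / (2 * n)
    if (dice > best) best <- dice
  }
  best
}

#' Count longitudinal grooves of a stone mask
#'
#' Builds the angular radius profile r(theta) averaged over the central 50\%
#' of the stone length (1 degree grid, per-slice centroids), detrends it by
#' its circular mean, and counts local minima whose prominence exceeds
#' `prominence_frac` of the mean radius.
#'
#' @inheritParams solid_metrics
#' @param prominence_frac Minimum groove prominence as a fraction of the mean
#'   radius (default 0.02).
#' @param n_theta Angular grid size.
#' @param smooth_bins Width (bins) of the circular moving-average smoother.
#' @return Integer groove count.
#' @export
count_grooves <- function(mask, prominence_frac = 0.02, n_theta = 360L,
                          smooth_bins = 9L) {
  if (!any(mask)) stop_olive("empty mask")
  co <- mask_coords(mask)
  zr <- range(co[, 3])
  zmid <- mean(zr); zhalf <- diff(zr) / 4
  # lateral boundary voxels of the central slices, radius relative to the
  # per-slice centroid and normalized by the per-slice mean radius (removes
  # axial taper); the angular profile is a circular Gaussian-kernel mean of
  # the boundary radii, which is free of lattice-direction comb artifacts
  shell <- boundary_shell(mask)
  cs <- mask_coords(shell)
  cs <- cs[cs[, 3] >= zmid - zhalf & cs[, 3] <= zmid + zhalf, , drop = FALSE]
  slices <- unique(cs[, 3])
  th_all <- numeric(0); r_all <- numeric(0)
  for (k in slices) {
    sel_full <- co[co[, 3] == k, 1:2, drop = FALSE]
    ctr <- colMeans(sel_full)
    p <- cs[cs[, 3] == k, 1:2, drop = FALSE]
    dxy <- sweep(p, 2, ctr)
    r <- sqrt(rowSums(dxy^2))
    th_all <- c(th_all, atan2(dxy[, 2], dxy[, 1]))
    r_all <- c(r_all, r / mean(r))
  }
  grid <- seq(-pi, pi, length.out = n_theta + 1)[seq_len(n_theta)]
  sd_rad <- (smooth_bins / 3) * 2 * pi / n_theta
  dmat <- outer(grid, th_all, `-`)
  dmat <- abs((dmat + pi) %% (2 * pi) - pi)
  wmat <- exp(-0.5 * (dmat / sd_rad)^2)
  r_theta <- as.numeric(wmat %*% r_all) / rowSums(wmat)
  # remove the first two circular harmonics (residual centroid offset and
  # cross-section ellipticity) so an elliptic but smooth stone counts zero;
  # grooves are assumed narrower than a half-turn
  H <- cbind(cos(grid), sin(grid), cos(2 * grid), sin(2 * grid))
  r_theta <- r_theta - H %*% qr.solve(H, r_theta - mean(r_theta))
  count_circular_minima(as.numeric(r_theta), prominence_frac * mean(r_theta))
}

circular_ma <- function(x, w) {
  if (w <= 1) return(x)
  r <- w %/% 2
  n <- length(x)
  xp <- c(tail(x, r), x, head(x, r))
  as.numeric(stats::filter(xp, rep(1 / (2 * r + 1), 2 * r + 1),
                           sides = 2))[(r + 1):(r + n)]
}

# local minima of a circular profile with at least the given prominence
count_circular_minima <- function(x, min_prom) {
  n <- length(x)
  prev <- c(tail(x, 1), head(x, -1))
  nxt <- c(tail(x, -1), head(x, 1))
  cand <- which(x < prev & x <= nxt)
  if (!length(cand)) return(0L)
  count <- 0L
  for (i in cand) {
    walk <- function(step) {
      top <- x[i]
      j <- i
      for (s in seq_len(n - 1)) {
        j <- ((j - 1 + step) %% n) + 1
        if (x[j] < x[i]) break
        if (x[j] > top) top <- x[j]
      }
      top
    }
    prom <- min(walk(1), walk(-1)) - x[i]
    if (prom >= min_prom) count <- count + 1L
  }
  count
}

#' Lenticel density on the fruit surface
#'
#' Samples the gray values of a one-voxel-deep surface shell, unwraps them to
#' a (theta, z) map, detects contrast blobs as local difference-of-Gaussian
#' extrema above a robust threshold, and reports blobs per cm^2.
#'
#' @param volume Aligned [volume3d()] (gray values).
#' @param fruit_mask Aligned fruit mask congruent with `volume`.
#' @param surface_area Fruit surface area in cm^2 (from [solid_metrics()]).
#' @param contrast_mult Detection threshold as a multiple of the MAD of the
#'   filtered map (default 6).
#' @param contrast_sign +1 to detect bright marks, -1 dark marks.
#' @param sigma1,sigma2 Difference-of-Gaussian scales (map cells), matched to
#'   the expected mark radius.
#' @return A list with `count` and `density` (cm^-2).
#' @export
lenticel_density <- function(volume, fruit_mask, surface_area,
                             contrast_mult = 6, contrast_sign = 1,
                             sigma1 = 1.5, sigma2 = 4) {
  shell <- boundary_shell(fruit_mask)
  if (!any(shell)) stop_olive("empty surface shell")
  co <- mask_coords(shell)
  g <- as.numeric(volume$voxels[co])
  zs <- sort(unique(co[, 3]))
  # per-slice centroid of the full mask (robust to bends)
  cent <- t(vapply(zs, function(k) {
    p <- mask_coords(fruit_mask[, , k, drop = FALSE])
    c(mean(p[, 1]), mean(p[, 2]))
  }, c(0, 0)))
  rownames(cent) <- zs
  ci <- match(co[, 3], zs)
  dx <- co[, 1] - cent[ci, 1]; dy <- co[, 2] - cent[ci, 2]
  th <- atan2(dy, dx)
  r_med <- median(sqrt(dx^2 + dy^2))
  n_th <- max(16L, as.integer(round(2 * pi * r_med)))
  tb <- pmin(n_th, 1L + as.integer(floor((th + pi) / (2 * pi) * n_th)))
  # mean shell gray per (z, theta) cell
  map <- matrix(NA_real_, length(zs), n_th)
  sums <- tapply(g, list(ci, tb), mean)
  map[cbind(as.integer(rep(rownames(sums), ncol(sums))),
            as.integer(rep(colnames(sums), each = nrow(sums))))] <- as.numeric(sums)
  med <- median(map, na.rm = TRUE)
  map[is.na(map)] <- med
  # difference of Gaussians with circular theta padding
  blur <- function(m, s) {
    r <- ceiling(3 * s)
    k <- stats::dnorm(-r:r, sd = s); k <- k / sum(k)
    mp <- cbind(m[, (n_th - r + 1):n_th, drop = FALSE], m,
                m[, 1:r, drop = FALSE])
    mp <- rbind(mp[rep(1, r), , drop = FALSE], mp,
                mp[rep(nrow(mp), r), , drop = FALSE])
    out <- apply(mp, 2, function(col) as.numeric(stats::filter(col, k, sides = 2)))
    out <- t(apply(out, 1, function(row) as.numeric(stats::filter(row, k, sides = 2))))
    out[(r + 1):(nrow(out) - r), (r + 1):(ncol(out) - r)]
  }
  D <- contrast_sign * (blur(map, sigma1) - blur(map, sigma2))
  thr <- contrast_mult * mad(D, na.rm = TRUE)
  # 8-neighbour local maxima with theta wraparound
  nr <- nrow(D); nc <- ncol(D)
  wrap <- function(m, dc) m[, ((seq_len(nc) - 1 + dc) %% nc) + 1, drop = FALSE]
  shift_r <- function(m, dr) {
    if (dr == 0) return(m)
    out <- matrix(-Inf, nr, nc)
    if (dr > 0) out[(1 + dr):nr, ] <- m[1:(nr - dr), ]
    else out[1:(nr + dr), ] <- m[(1 - dr):nr, ]
    out
  }
  ismax <- D >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & (D > shift_r(wrap(D, dc), dr) - 1e-12)
  }
  count <- sum(ismax, na.rm = TRUE)
  list(count = count, density = count / surface_area)
}

#' Rugosity index of a stone mask
#'
#' Ratio of the triangulated isosurface area to the convex-hull surface area
#' (Cauchy projection estimate); about 1 for convex smooth stones, larger for
#' grooved ones.
#'
#' @inheritParams solid_metrics
#' @return Unitless index (>= ~1).
#' @export
rugosity_index <- function(mask, smooth_sigma = 1) {
  if (!any(mask)) stop_olive("empty mask")
  iso <- mask_isosurface(mask, smooth_sigma)
  hull <- convex_hull_area(mask_coords(boundary_shell(mask)))
  iso$area / hull
}

# --- whole-olive measurement --------------------------------------------------

#' Measure all morphometric traits of one segmented olive
#'
#' Applies the trait extractors to fruit (D), stone (E) and cavity (C): size
#' and shape metrics, position of the maximum transverse area, bilateral
#' asymmetry, groove count and rugosity of the stone, lenticel density of the
#' fruit, and density-derived weights. Fruit/stone traits are reported in
#' cm/cm^2/cm^3, cavity traits in mm/mm^2/mm^3.
#'
#' @param volume A [volume3d()] (unaligned is fine; the fruit's principal-axis
#'   transform is applied internally and each compartment is then aligned to
#'   its own long axis).
#' @param masks A [segmentation_masks()] congruent with `volume`.
#' @param olive_id Optional id carried into the output row.
#' @param fruit_density,stone_density g/cm^3 used to derive weights from
#'   volumes.
#' @param asymmetry_step_deg Mirror-sweep azimuth step.
#' @param apex Apex orientation rule passed to the aligners (use `"+z"` when
#'   the source volume is known to have its apex toward +z, e.g. phantoms).
#' @param lenticel_args List of extra arguments for [lenticel_density()].
#' @return One-row tibble with the 24 trait columns (see [trait_names()]).
#' @export
measure_olive <- function(volume, masks, olive_id = NULL,
                          fruit_density = 0.96, stone_density = 1.07,
                          asymmetry_step_deg = 1, lenticel_args = list(),
                          apex = "auto") {
  if (is.null(masks$alignment)) {
    al <- align_segmentation(masks, volume, apex = apex)
    masks <- al$masks; volume <- al$volume
  }
  vs <- volume$voxel_size
  D <- solid_metrics(masks$fruit, vs)
  lent <- do.call(lenticel_density,
                  c(list(volume = volume, fruit_mask = masks$fruit,
                         surface_area = D$surface_area / 100), lenticel_args))
  stone_al <- align_to_major_axis(masks$stone, apex = "+z")$mask
  E <- solid_metrics(stone_al, vs)
  has_cavity <- any(masks$cavity)
  if (has_cavity) {
    cav_al <- align_to_major_axis(masks$cavity, apex = "+z")$mask
    C <- solid_metrics(cav_al, vs)
  }
  row <- tibble(
    D_Volume = D$volume / 1000, D_Surface_area = D$surface_area / 100,
    D_Sphericity = D$sphericity, D_L_W = D$L_W,
    D_Asymmetry_coefficient = asymmetry_coefficient(masks$fruit, asymmetry_step_deg),
    D_Position_of_MTA = position_of_mta(masks$fruit),
    D_Weight = fruit_density * D$volume / 1000,
    D_Lenticel_density = lent$density,
    E_Volume = E$volume / 1000, E_Surface_area = E$surface_area / 100,
    E_Sphericity = E$sphericity, E_L_W = E$L_W,
    E_Asymmetry_coefficient = asymmetry_coefficient(stone_al, asymmetry_step_deg),
    E_Position_of_MTA = position_of_mta(stone_al),
    E_Weight = stone_density * E$volume / 1000,
    E_Number_of_grooves = count_grooves(stone_al),
    C_Volume = if (has_cavity) C$volume else 0,
    C_Surface_area = if (has_cavity) C$surface_area else 0,
    C_Width = if (has_cavity) C$W else 0,
    C_Sphericity = if (has_cavity) C$sphericity else NA_real_,
    C_Height = if (has_cavity) C$height else 0,
    C_L_W = if (has_cavity) C$L_W else NA_real_,
    C_Flat = if (has_cavity) C$flatness else NA_real_,
    C_Position_of_MTA = if (has_cavity) position_of_mta(cav_al) else NA_real_
  )
  row$E_Rugosity_index <- rugosity_index(stone_al)
  if (!is.null(olive_id)) row <- bind_cols(tibble(olive_id = olive_id), row)
  row
}
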