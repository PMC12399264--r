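#' Specify a synthetic drupe phantom
#'
#' A phantom is a voxelized model of one olive: an ovoid fruit (mesocarp)
#' containing a grooved stone (endocarp) which in turn contains a smooth
#' internal cavity. The fruit's axial profile places the maximum transverse
#' area at a configurable offset, an optional chiral bend displaces the
#' midline (breaking every axial mirror plane so the bilateral-asymmetry
#' coefficient responds to it), and lenticel-like contrast marks are seeded on
#' the fruit surface. Three gray-level populations (background/cavity,
#' mesocarp, stone) are separable by thresholding.
#'
#' @param fruit_semi_axes,stone_semi_axes Semi-axes `(a, b, c)` in mm; `c` is
#'   the half-length along the long axis (+z = apex).
#' @param cavity_scale Fractions of the stone semi-axes (length 1 or 3); the
#'   cavity must fit strictly inside the grooved stone, so
#'   `max(cavity_scale) < 1 - groove_depth`.
#' @param groove_count,groove_depth Number of longitudinal grooves on the
#'   stone and their depth as a fraction of the local stone radius.
#' @param bend_angle Degrees; apex-ward midline deflection (0 = straight).
#' @param mta_offset Position of the maximum transverse area, signed percent
#'   of total length from mid-body (positive toward the apex).
#' @param lenticel_count,lenticel_contrast Number of disc-shaped surface marks
#'   and their gray-level offset relative to the mesocarp.
#' @param lenticel_radius_mm Radius of each mark in mm.
#' @param gray_model Named list with `background`, `cavity`, `mesocarp`,
#'   `stone`, each `c(mean, sd)` on an 8-bit scale. Means must be ordered
#'   background <= cavity < mesocarp < stone.
#' @param voxel_size Isotropic voxel size in micrometres.
#' @param seed Integer seed for the gray-level noise and lenticel placement.
#' @param max_voxels Guard on the voxel budget of the generated grid.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(fruit_semi_axes = c(6.5, 6.2, 10),
                         stone_semi_axes = c(3.2, 3.0, 7),
                         cavity_scale = c(0.55, 0.45, 0.75),
                         groove_count = 0L, groove_depth = 0.05,
                         bend_angle = 0, mta_offset = 0,
                         lenticel_count = 0L, lenticel_contrast = 45,
                         lenticel_radius_mm = 0.45,
                         gray_model = default_gray_model(),
                         voxel_size = 200, seed = 1L,
                         max_voxels = 4e6) {
  stopifnot(length(fruit_semi_axes) == 3, length(stone_semi_axes) == 3)
  if (length(cavity_scale) == 1) cavity_scale <- rep(cavity_scale, 3)
  stopifnot(length(cavity_scale) == 3)
  check_number(voxel_size, "voxel_size", lower = 1e-6)
  check_number(groove_depth, "groove_depth", lower = 0, upper = 0.5)
  check_number(mta_offset, "mta_offset", lower = -40, upper = 40)
  if (any(stone_semi_axes >= fruit_semi_axes)) {
    stop_olive("stone must fit strictly inside the fruit (semi-axis-wise)")
  }
  if (any(cavity_scale < 0) ||
      any(cavity_scale >= 1 - (groove_count > 0) * groove_depth)) {
    stop_olive("cavity must fit strictly inside the grooved stone")
  }
  gm <- gray_model
  for (nm in c("background", "cavity", "mesocarp", "stone")) {
    if (is.null(gm[[nm]]) || length(gm[[nm]]) != 2) {
      stop_olive("gray_model must provide c(mean, sd) for ", nm)
    }
  }
  mns <- vapply(gm[c("background", "cavity", "mesocarp", "stone")], `[`, 0, 1)
  if (is.unsorted(mns)) {
    stop_olive("gray means must be ordered background <= cavity < mesocarp < stone")
  }
  spec <- structure(
    list(fruit_semi_axes = fruit_semi_axes, stone_semi_axes = stone_semi_axes,
         cavity_scale = cavity_scale, groove_count = as.integer(groove_count),
         groove_depth = groove_depth, bend_angle = bend_angle,
         mta_offset = mta_offset, lenticel_count = as.integer(lenticel_count),
         lenticel_contrast = lenticel_contrast,
         lenticel_radius_mm = lenticel_radius_mm,
         gray_model = gm, voxel_size = voxel_size, seed = as.integer(seed),
         max_voxels = max_voxels),
    class = "phantom_spec"
  )
  dims <- phantom_grid_dims(spec)
  if (prod(dims) > max_voxels) {
    stop_olive(sprintf("phantom grid %s exceeds the voxel budget (%g)",
                       paste(dims, collapse = "x"), max_voxels))
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> fruit (%.1f, %.1f, %.1f) mm, stone ",
                     "(%.1f, %.1f, %.1f) mm, %d grooves, bend %.0f deg, ",
                     "voxel %.0f um\n"),
              x$fruit_semi_axes[1], x$fruit_semi_axes[2], x$fruit_semi_axes[3],
              x$stone_semi_axes[1], x$stone_semi_axes[2], x$stone_semi_axes[3],
              x$groove_count, x$bend_angle, x$voxel_size))
  invisible(x)
}

default_gray_model <- function() {
  list(background = c(30, 5), cavity = c(35, 5),
       mesocarp = c(110, 8), stone = c(200, 10))
}

phantom_margin_mm <- function(spec) {
  # lateral clearance for the bend plus a 3-voxel border
  bend_off <- spec$fruit_semi_axes[3] * tan(spec$bend_angle * pi / 180)
  bend_off + 3 * spec$voxel_size / 1000
}

phantom_grid_dims <- function(spec) {
  mm <- spec$voxel_size / 1000
  half <- spec$fruit_semi_axes + phantom_margin_mm(spec)
  as.integer(2 * ceiling(half / mm) + 1L)
}

# axial radius profile: unit half-ellipses joined at t = tstar (the slice of
# maximum transverse area), t = z / c in [-1, 1]
axial_profile <- function(t, tstar) {
  span <- ifelse(t >= tstar, 1 - tstar, 1 + tstar)
  sqrt(pmax(0, 1 - ((t - tstar) / span)^2))
}

# chiral midline displacement: magnitude grows toward the apex, direction
# twists with height so no axial mirror plane survives
midline_offset <- function(z, c_fruit, bend_angle) {
  t <- z / c_fruit
  mag <- c_fruit * tan(bend_angle * pi / 180) / 4 * (1 + t)^2
  az <- 2 * pi / 3 * (t + 1) / 2
  cbind(mag * cos(az), mag * sin(az))
}

groove_modulation <- function(theta, k, depth) {
  if (k <= 0 || depth <= 0) return(rep_len(1, length(theta)))
  1 - depth * pmax(0, cos(k * theta))^2
}

#' Generate a voxel drupe phantom with ground truth
#'
#' Voxelizes a [phantom_spec()] into a gray-level volume plus exact masks and
#' reference trait values (analytic or high-resolution quadrature).
#'
#' @param spec A `phantom_spec`.
#' @return A list with elements `volume` (a [volume3d()]) and `truth`: masks
#'   (`fruit`, `stone`, `cavity`), reference traits (`true_traits`), the
#'   seeded lenticel coordinates (`lenticels`), and `groove_count`.
#' @export
generate_drupe_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mm <- spec$voxel_size / 1000
  dims <- phantom_grid_dims(spec)
  ax_f <- spec$fruit_semi_axes
  ax_s <- spec$stone_semi_axes
  ax_c <- spec$stone_semi_axes * spec$cavity_scale
  tstar <- 2 * spec$mta_offset / 100  # percent of L -> fraction of c

  # voxel-center coordinates in mm, centered on the grid
  xs <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * mm
  ys <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * mm
  zs <- (seq_len(dims[3]) - (dims[3] + 1) / 2) * mm

  fruit <- array(FALSE, dims); stone <- array(FALSE, dims); cavity <- array(FALSE, dims)
  for (k in seq_along(zs)) {
    z <- zs[k]
    off <- midline_offset(z, ax_f[3], spec$bend_angle)
    dx <- xs - off[1]; dy <- ys - off[2]
    tf <- z / ax_f[3]
    if (abs(tf) < 1) {
      g <- axial_profile(tf, tstar)
      if (g > 0) {
        q <- outer((dx / (ax_f[1] * g))^2, (dy / (ax_f[2] * g))^2, `+`)
        fruit[, , k] <- q <= 1
      }
    }
    ts <- z / ax_s[3]
    if (abs(ts) < 1) {
      gs <- axial_profile(ts, 0)
      if (gs > 0) {
        if (spec$groove_count > 0) {
          th <- atan2(outer(rep_len(1, length(dx)), dy), outer(dx, rep_len(1, length(dy))))
          mmod <- 1 - spec$groove_depth * pmax(0, cos(spec$groove_count * th))^2
        } else mmod <- 1
        q <- outer((dx / (ax_s[1] * gs))^2, (dy / (ax_s[2] * gs))^2, `+`) / mmod^2
        stone[, , k] <- q <= 1
      }
    }
    tc <- if (all(ax_c > 0)) z / ax_c[3] else Inf
    if (abs(tc) < 1) {
      gc <- axial_profile(tc, 0)
      if (gc > 0) {
        q <- outer((dx / (ax_c[1] * gc))^2, (dy / (ax_c[2] * gc))^2, `+`)
        cavity[, , k] <- q <= 1
      }
    }
  }

  with_seed(spec$seed, {
    gm <- spec$gray_model
    vox <- array(rnorm(prod(dims), gm$background[1], gm$background[2]), dims)
    meso <- fruit & !stone
    solid <- stone & !cavity
    vox[meso]   <- rnorm(sum(meso), gm$mesocarp[1], gm$mesocarp[2])
    vox[solid]  <- rnorm(sum(solid), gm$stone[1], gm$stone[2])
    vox[cavity] <- rnorm(sum(cavity), gm$cavity[1], gm$cavity[2])

    lenticels <- seed_lenticels(spec, xs, ys, zs, tstar)
    if (nrow(lenticels)) {
      r_l <- spec$lenticel_radius_mm
      for (i in seq_len(nrow(lenticels))) {
        p <- as.numeric(lenticels[i, c("x", "y", "z")])
        ix <- which(abs(xs - p[1]) <= r_l); iy <- which(abs(ys - p[2]) <= r_l)
        iz <- which(abs(zs - p[3]) <= r_l)
        sub <- expand.grid(ix = ix, iy = iy, iz = iz)
        d2 <- (xs[sub$ix] - p[1])^2 + (ys[sub$iy] - p[2])^2 + (zs[sub$iz] - p[3])^2
        sel <- sub[d2 <= r_l^2, ]
        idx <- cbind(sel$ix, sel$iy, sel$iz)
        inmeso <- meso[idx]
        vox[idx[inmeso, , drop = FALSE]] <-
          vox[idx[inmeso, , drop = FALSE]] + spec$lenticel_contrast
      }
    }
    vox <- array(as.integer(pmin(255, pmax(0, round(vox)))), dims)

    volume <- volume3d(vox, voxel_size = spec$voxel_size,
                       provenance = list(source = "phantom", seed = spec$seed))
    truth <- list(
      fruit = fruit, stone = stone, cavity = cavity,
      lenticels = lenticels, groove_count = spec$groove_count,
      true_traits = phantom_true_traits(spec)
    )
    list(volume = volume, truth = truth)
  })
}

# lenticel centers on the fruit surface, restricted to the central band and
# separated by at least 3 mark radii (so detected blobs stay countable)
seed_lenticels <- function(spec, xs, ys, zs, tstar) {
  n <- spec$lenticel_count
  empty <- tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                  theta = numeric(0))
  if (n <= 0) return(empty)
  ax <- spec$fruit_semi_axes
  min_sep <- 3 * spec$lenticel_radius_mm
  pts <- matrix(NA_real_, 0, 3)
  thetas <- numeric(0)
  attempts <- 0L
  while (nrow(pts) < n && attempts < 400L * n) {
    attempts <- attempts + 1L
    t <- runif(1, -0.8, 0.8)
    th <- runif(1, -pi, pi)
    g <- axial_profile(t, tstar)
    off <- midline_offset(t * ax[3], ax[3], spec$bend_angle)
    p <- c(off[1] + ax[1] * g * cos(th), off[2] + ax[2] * g * sin(th), t * ax[3])
    if (nrow(pts) > 0 &&
        min(sqrt(rowSums(sweep(pts, 2, p)^2))) < min_sep) next
    pts <- rbind(pts, p)
    thetas <- c(thetas, th)
  }
  tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3], theta = thetas)
}

# reference trait values by high-resolution quadrature on the parametric
# surface (exact up to quadrature error, independent of the voxel grid)
phantom_true_traits <- function(spec, nt = 600, nth = 720) {
  tstar <- 2 * spec$mta_offset / 100
  solid_truth <- function(ax, tstar, k = 0, depth = 0, bend = 0) {
    tt <- seq(-1, 1, length.out = nt + 1)
    th <- seq(0, 2 * pi, length.out = nth + 1)
    g <- axial_profile(tt, tstar)
    m <- groove_modulation(th, k, depth)
    # cross-section area factor: (1/2) int m^2 r^2 dtheta for unit ellipse
    m2 <- pracma::trapz(th, m^2) / (2 * pi)
    A <- pi * ax[1] * ax[2] * g^2 * m2
    V <- pracma::trapz(tt * ax[3], A)
    # parametric surface, including bend
    off <- midline_offset(tt * ax[3], spec$fruit_semi_axes[3], bend)
    X <- outer(m * cos(th), g * ax[1]) + matrix(off[, 1], nth + 1, nt + 1, byrow = TRUE)
    Y <- outer(m * sin(th), g * ax[2]) + matrix(off[, 2], nth + 1, nt + 1, byrow = TRUE)
    Z <- matrix(tt * ax[3], nth + 1, nt + 1, byrow = TRUE)
    S <- mesh_area(X, Y, Z)
    sph <- pi^(1 / 3) * (6 * V)^(2 / 3) / S
    list(volume = V, surface_area = S, sphericity = sph,
         L = 2 * ax[3], W = 2 * max(ax[1], ax[2]),
         L_W = ax[3] / max(ax[1], ax[2]),
         height = 2 * min(ax[1], ax[2]),
         flatness = min(ax[1], ax[2]) / max(ax[1], ax[2]),
         mta = spec$mta_offset * (tstar != 0))
  }
  list(
    fruit = solid_truth(spec$fruit_semi_axes, tstar, bend = spec$bend_angle),
    stone = solid_truth(spec$stone_semi_axes, 0, spec$groove_count,
                        spec$groove_depth, bend = spec$bend_angle),
    cavity = if (all(spec$cavity_scale > 0)) {
      solid_truth(spec$stone_semi_axes * spec$cavity_scale, 0,
                  bend = spec$bend_angle)
    } else NULL
  )
}

# total area of a quad mesh given coordinate matrices (triangulated)
mesh_area <- function(X, Y, Z) {
  i <- seq_len(nrow(X) - 1); j <- seq_len(ncol(X) - 1)
  ax <- X[i, j]; ay <- Y[i, j]; az <- Z[i, j]
  bx <- X[i + 1, j]; by <- Y[i + 1, j]; bz <- Z[i + 1, j]
  cx <- X[i + 1, j + 1]; cy <- Y[i + 1, j + 1]; cz <- Z[i + 1, j + 1]
  dx <- X[i, j + 1]; dy <- Y[i, j + 1]; dz <- Z[i, j + 1]
  tri <- function(x1, y1, z1, x2, y2, z2, x3, y3, z3) {
    ux <- x2 - x1; uy <- y2 - y1; uz <- z2 - z1
    vx <- x3 - x1; vy <- y3 - y1; vz <- z3 - z1
    nx <- uy * vz - uz * vy; ny <- uz * vx - ux * vz; nz <- ux * vy - uy * vx
    0.5 * sqrt(nx^2 + ny^2 + nz^2)
  }
  sum(tri(ax, ay, az, bx, by, bz, cx, cy, cz)) +
    sum(tri(ax, ay, az, cx, cy, cz, dx, dy, dz))
}
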