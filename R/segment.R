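#' Gray-level histogram of a volume
#'
#' @param x A [volume3d()] or numeric array/vector of gray values.
#' @param levels Gray levels to tabulate over (default `0:255`).
#' @return Named integer vector of counts, one per level.
#' @export
gray_histogram <- function(x, levels = 0:255) {
  if (inherits(x, "volume3d")) x <- x$voxels
  v <- round(as.numeric(x))
  counts <- tabulate(match(v, levels), nbins = length(levels))
  setNames(counts, levels)
}

#' Otsu threshold of a gray-level histogram
#'
#' Returns the gray level maximizing the between-class variance of the
#' two-class split (levels `<= t` versus `> t`). Ties are broken toward the
#' lowest level.
#'
#' @param counts Non-negative counts per gray level (histogram), or a
#'   [volume3d()] whose histogram is taken first.
#' @param levels Gray levels corresponding to `counts`; defaults to the
#'   histogram names or `0:(length-1)`.
#' @return The threshold level; voxels strictly above it form the
#'   high-intensity class.
#' @export
otsu_threshold <- function(counts, levels = NULL) {
  if (inherits(counts, "volume3d")) counts <- gray_histogram(counts)
  if (is.null(levels)) {
    levels <- if (!is.null(names(counts))) as.numeric(names(counts))
              else seq_along(counts) - 1
  }
  stopifnot(length(levels) == length(counts))
  ord <- order(levels)
  levels <- levels[ord]; counts <- as.numeric(counts[ord])
  nz <- which(counts > 0)
  if (length(nz) < 2) {
    stop_olive("degenerate histogram: need at least two occupied gray levels")
  }
  n <- sum(counts)
  w0 <- cumsum(counts) / n
  mu <- cumsum(counts * levels) / n
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, length(levels))
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  levels[which.max(sigma_b)]  # which.max takes the first (lowest) maximizer
}

# two-threshold single-pass variant (three classes), exhaustive maximization
# of between-class variance over ordered threshold pairs
otsu_threshold2 <- function(counts, levels = NULL) {
  if (is.null(levels)) {
    levels <- if (!is.null(names(counts))) as.numeric(names(counts))
              else seq_along(counts) - 1
  }
  counts <- as.numeric(counts)
  n <- sum(counts)
  cw <- cumsum(counts); cm <- cumsum(counts * levels)
  class_stat <- function(i, j) {  # class = levels (i..j]
    w <- (cw[j] - if (i > 0) cw[i] else 0) / n
    m <- (cm[j] - if (i > 0) cm[i] else 0) / n
    c(w, m)
  }
  K <- length(levels)
  best <- c(-Inf, NA, NA)
  for (i in 1:(K - 2)) for (j in (i + 1):(K - 1)) {
    s1 <- class_stat(0, i); s2 <- class_stat(i, j); s3 <- class_stat(j, K)
    if (s1[1] == 0 || s2[1] == 0 || s3[1] == 0) next
    mu_t <- cm[K] / n
    v <- s1[2]^2 / s1[1] + s2[2]^2 / s2[1] + s3[2]^2 / s3[1] - mu_t^2
    if (v > best[1]) best <- c(v, levels[i], levels[j])
  }
  if (!is.finite(best[1])) stop_olive("degenerate histogram for 3-class Otsu")
  best[2:3]
}

label_components <- function(mask, connectivity = 6L) {
  labs <- .cc_label_3d(as.logical(mask), dim(mask), as.integer(connectivity))
  array(labs, dim(mask))
}

largest_component <- function(mask, connectivity = 6L) {
  labs <- label_components(mask, connectivity)
  sizes <- tabulate(labs)
  if (!length(sizes)) return(array(FALSE, dim(mask)))
  array(labs == which.max(sizes), dim(mask))
}

# fill internal holes: background components not connected to the grid border
fill_holes <- function(mask) {
  bg <- !mask
  labs <- label_components(bg, 6L)
  d <- dim(mask)
  border_labels <- unique(c(labs[c(1, d[1]), , ], labs[, c(1, d[2]), ],
                            labs[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0]
  holes <- bg & !(labs %in% border_labels)
  mask | array(holes, d)
}

drop_small_components <- function(mask, min_voxels, connectivity = 6L) {
  labs <- label_components(mask, connectivity)
  sizes <- tabulate(labs)
  keep <- which(sizes >= min_voxels)
  array(labs %in% keep, dim(mask))
}

#' Segmentation masks of one drupe
#'
#' @param fruit,stone,cavity Congruent logical arrays (cavity inside stone
#'   inside fruit).
#' @param alignment Optional rigid alignment transform (see
#'   [align_to_major_axis()]).
#' @param thresholds Gray thresholds used during segmentation, if any.
#' @return A `segmentation_masks` object.
#' @export
segmentation_masks <- function(fruit, stone, cavity, alignment = NULL,
                               thresholds = NULL) {
  stopifnot(identical(dim(fruit), dim(stone)), identical(dim(fruit), dim(cavity)))
  if (any(stone & !fruit)) stop_olive("stone mask must be contained in the fruit mask")
  if (any(cavity & !stone)) stop_olive("cavity mask must be contained in the stone mask")
  structure(list(fruit = fruit, stone = stone, cavity = cavity,
                 alignment = alignment, thresholds = thresholds),
            class = "segmentation_masks")
}

#' @export
print.segmentation_masks <- function(x, ...) {
  cat(sprintf("<segmentation_masks> fruit %d, stone %d, cavity %d voxels\n",
              sum(x$fruit), sum(x$stone), sum(x$cavity)))
  invisible(x)
}

#' Segment a drupe volume into fruit, stone and cavity
#'
#' Hierarchical two-pass Otsu thresholding: a first threshold on the full
#' histogram separates the drupe from the background; a second threshold,
#' restricted to drupe voxels, separates the dense stone from the mesocarp.
#' The fruit is the hole-filled largest foreground component, the stone the
#' hole-filled largest high-intensity component, and the cavity the internal
#' background-level holes of the unfilled stone. Components smaller than
#' `min_component_frac` of the object volume are discarded.
#'
#' @param volume A [volume3d()] containing exactly one drupe on background.
#' @param min_component_frac Discard components below this fraction of the
#'   object volume (default 0.0001, i.e. 0.01\%).
#' @param three_class Use a single-pass two-threshold (3-class) Otsu instead
#'   of the hierarchical variant.
#' @return A [segmentation_masks()] object (unaligned; see
#'   [align_to_major_axis()]).
#' @export
segment_drupe <- function(volume, min_component_frac = 1e-4,
                          three_class = FALSE) {
  stopifnot(inherits(volume, "volume3d"))
  vox <- volume$voxels
  h <- gray_histogram(vox)
  if (three_class) {
    tt <- otsu_threshold2(h)
    t1 <- tt[1]; t2 <- tt[2]
  } else {
    t1 <- otsu_threshold(h)
  }
  object <- vox > t1
  if (!any(object)) stop_olive("no foreground found above the Otsu threshold")
  # a drupe on background separates almost perfectly; a unimodal (empty)
  # volume does not get past Otsu effectiveness ~0.75
  lv <- as.numeric(names(h)); cnt <- as.numeric(h)
  mu <- sum(lv * cnt) / sum(cnt)
  tot_var <- sum(cnt * (lv - mu)^2) / sum(cnt)
  w0 <- sum(cnt[lv <= t1]) / sum(cnt)
  mu0 <- sum(lv[lv <= t1] * cnt[lv <= t1]) / max(1, sum(cnt[lv <= t1]))
  mu1 <- sum(lv[lv > t1] * cnt[lv > t1]) / max(1, sum(cnt[lv > t1]))
  eta <- w0 * (1 - w0) * (mu1 - mu0)^2 / tot_var
  if (!is.finite(eta) || eta < 0.75) {
    stop_olive("no foreground found: gray levels are not separable from background")
  }
  fruit <- fill_holes(largest_component(object))
  if (!three_class) {
    h2 <- gray_histogram(vox[fruit & object])
    t2 <- otsu_threshold(h2)
  }
  min_vox <- max(1, ceiling(min_component_frac * sum(fruit)))
  stone_raw <- fruit & (vox > t2)
  if (!any(stone_raw)) stop_olive("no stone voxels found above the second threshold")
  stone_raw <- largest_component(stone_raw)
  stone <- fill_holes(stone_raw)
  cavity <- stone & !stone_raw
  if (any(cavity)) cavity <- drop_small_components(cavity, min_vox)
  if (any(stone & !fruit)) stop_olive("stone not strictly inside fruit")
  segmentation_masks(fruit, stone, cavity,
                     thresholds = c(background = t1, stone = t2))
}

#' Align a mask to its principal long axis
#'
#' Computes the voxel second-moment tensor, rotates the mask so the
#' largest-eigenvalue axis lies on +z (nearest-neighbour resampling), and
#' orients +z toward the apex, defined as the end with the smaller mean
#' transverse cross-sectional area.
#'
#' @param mask Logical 3-D array (non-empty, more than one voxel).
#' @param apex Apex orientation rule: `"auto"` (smaller transverse area ends
#'   up at +z), or `"+z"` / `"-z"` when the apex direction is known in source
#'   coordinates (e.g. phantom ground truth), which takes precedence.
#' @return A list with `mask` (aligned array) and `transform` (rotation
#'   matrix, center, output dims; apply to congruent arrays with
#'   [apply_alignment()]).
#' @export
align_to_major_axis <- function(mask, apex = c("auto", "+z", "-z")) {
  apex <- match.arg(apex)
  idx <- which(mask)
  if (length(idx) < 2) stop_olive("degenerate mask: need at least two voxels")
  co <- arrayInd(idx, dim(mask))
  ctr <- colMeans(co)
  cv <- cov(co)
  if (any(!is.finite(cv)) || sum(diag(cv)) <= 0) {
    stop_olive("degenerate moment tensor")
  }
  eg <- eigen(cv, symmetric = TRUE)
  # columns: new x, y from the minor axes, new z = major axis
  B <- cbind(eg$vectors[, 2], eg$vectors[, 3], eg$vectors[, 1])
  if (det(B) < 0) B[, 2] <- -B[, 2]
  U <- sweep(co, 2, ctr) %*% B
  rng <- apply(U, 2, range)
  pad <- 2
  dims_out <- as.integer(ceiling(rng[2, ] - rng[1, ]) + 2 * pad + 1)
  origin <- rng[1, ] - pad  # aligned coordinate of output voxel (1,1,1)
  origin_z_flip <- -rng[2, 3] - pad  # z origin of the mirrored grid
  tr <- list(rotation = B, center = ctr, origin = origin,
             origin_z_flip = origin_z_flip, dims_out = dims_out,
             flip = FALSE)
  if (apex == "auto") {
    aligned <- apply_alignment(mask, tr)
    # apex (+z) = end with smaller transverse area
    prof <- apply(aligned, 3, sum)
    nz <- which(prof > 0)
    qn <- max(1L, floor(length(nz) / 4))
    lo <- mean(prof[nz[seq_len(qn)]])
    hi <- mean(prof[nz[seq(length(nz) - qn + 1, length(nz))]])
    if (hi > lo) {
      tr$flip <- TRUE
      aligned <- apply_alignment(mask, tr)
    }
  } else {
    # known apex direction in source coordinates takes precedence
    src_up_maps_to <- B[3, 3]
    tr$flip <- if (apex == "+z") src_up_maps_to < 0 else src_up_maps_to > 0
    aligned <- apply_alignment(mask, tr)
  }
  list(mask = aligned, transform = tr)
}

#' Apply a rigid alignment transform to a congruent array
#'
#' Resamples `arr` on the aligned grid produced by [align_to_major_axis()]
#' using nearest-neighbour interpolation (masks stay boolean).
#'
#' @param arr Logical or numeric 3-D array congruent with the mask the
#'   transform was computed from.
#' @param transform Transform list from [align_to_major_axis()].
#' @param fill Value for voxels mapping outside the source grid.
#' @return Array of dims `transform$dims_out`.
#' @export
apply_alignment <- function(arr, transform, fill = if (is.logical(arr)) FALSE else 0) {
  d_in <- dim(arr)
  d_out <- transform$dims_out
  g1 <- seq_len(d_out[1]) - 1 + transform$origin[1]
  g2 <- seq_len(d_out[2]) - 1 + transform$origin[2]
  if (transform$flip) {
    # mirrored grid: output coord v has source aligned coord -v
    g3 <- -(seq_len(d_out[3]) - 1 + transform$origin_z_flip)
  } else {
    g3 <- seq_len(d_out[3]) - 1 + transform$origin[3]
  }
  # aligned coords -> source coords: x = center + B %*% u
  out <- array(fill, d_out)
  Bt <- t(transform$rotation)
  U <- cbind(rep(g1, times = d_out[2] * d_out[3]),
             rep(rep(g2, each = d_out[1]), times = d_out[3]),
             rep(g3, each = d_out[1] * d_out[2]))
  S <- U %*% Bt
  i <- as.integer(round(S[, 1] + transform$center[1]))
  j <- as.integer(round(S[, 2] + transform$center[2]))
  k <- as.integer(round(S[, 3] + transform$center[3]))
  ok <- i >= 1 & i <= d_in[1] & j >= 1 & j <= d_in[2] & k >= 1 & k <= d_in[3]
  out[ok] <- arr[cbind(i[ok], j[ok], k[ok])]
  out
}

#' Align all masks (and optionally the gray volume) of a segmentation
#'
#' The fruit's principal-axis transform is applied to fruit, stone and cavity
#' so the three masks stay congruent.
#'
#' @param masks A [segmentation_masks()].
#' @param volume Optional [volume3d()] to resample with the same transform.
#' @param apex Apex orientation rule, see [align_to_major_axis()].
#' @return A `segmentation_masks` with `alignment` set; if `volume` is given,
#'   a list with elements `masks` and `volume`.
#' @export
align_segmentation <- function(masks, volume = NULL, apex = "auto") {
  al <- align_to_major_axis(masks$fruit, apex = apex)
  tr <- al$transform
  out <- segmentation_masks(al$mask,
                            apply_alignment(masks$stone, tr),
                            apply_alignment(masks$cavity, tr),
                            alignment = tr, thresholds = masks$thresholds)
  if (is.null(volume)) return(out)
  vol_al <- volume3d(apply_alignment(volume$voxels, tr),
                     voxel_size = volume$voxel_size,
                     provenance = c(volume$provenance, list(aligned = TRUE)))
  list(masks = out, volume = vol_al)
}

#' Alignment transform as a 4x4 affine matrix
#'
#' @param transform Transform from [align_to_major_axis()].
#' @return 4x4 matrix mapping homogeneous source voxel indices to aligned
#'   voxel indices.
#' @export
alignment_affine <- function(transform) {
  B <- transform$rotation
  R <- t(B)  # source -> aligned rotation
  if (transform$flip) R[3, ] <- -R[3, ]
  orig <- transform$origin
  if (transform$flip) orig[3] <- -(orig[3] + transform$dims_out[3] - 1)
  shift <- -as.numeric(R %*% transform$center) - orig + 1
  rbind(cbind(R, shift), c(0, 0, 0, 1))
}
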