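#' Default trait correlation matrix
#'
#' Within-cultivar correlation structure used by the synthetic trait sampler.
#' The published tables carry no covariances, so this is an assumed structure:
#' strong coupling between each object's volume, surface area and weight
#' (volume-surface 0.95, volume-weight 0.98, surface-weight 0.93), moderate
#' coupling (0.6) between fruit-size and stone-size traits, zero elsewhere.
#' The matrix is projected to the nearest positive-definite correlation matrix
#' before use.
#'
#' @param traits Trait names the matrix should cover.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
default_trait_correlation <- function(traits = trait_names()) {
  p <- length(traits)
  R <- diag(p)
  dimnames(R) <- list(traits, traits)
  set_pair <- function(a, b, r) {
    if (a %in% traits && b %in% traits) {
      R[a, b] <<- r
      R[b, a] <<- r
    }
  }
  for (obj in c("D", "E", "C")) {
    vol <- paste0(obj, "_Volume"); sa <- paste0(obj, "_Surface_area")
    wt  <- paste0(obj, "_Weight")
    set_pair(vol, sa, 0.95)
    set_pair(vol, wt, 0.98)
    set_pair(sa,  wt, 0.93)
  }
  size_D <- intersect(c("D_Volume", "D_Surface_area", "D_Weight"), traits)
  size_E <- intersect(c("E_Volume", "E_Surface_area", "E_Weight"), traits)
  for (a in size_D) for (b in size_E) if (R[a, b] == 0) { R[a, b] <- 0.6; R[b, a] <- 0.6 }
  R
}

# nearest positive-definite correlation matrix (identity passes through)
nearest_pd_correlation <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-8) return(R)
  out <- as.matrix(Matrix::nearPD(R, corr = TRUE, do2eigen = TRUE)$mat)
  dimnames(out) <- dimnames(R)
  out
}

check_correlation_spec <- function(correlation, traits) {
  if (is.null(correlation)) correlation <- default_trait_correlation(traits)
  if (!is.matrix(correlation)) stop_olive("correlation must be a matrix")
  cn <- colnames(correlation)
  if (is.null(cn)) stop_olive("correlation matrix must carry trait names")
  unknown <- setdiff(cn, traits)
  if (length(unknown)) {
    stop_olive("unknown trait name(s) in correlation spec: ",
               paste(unknown, collapse = ", "))
  }
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-10))) {
    stop_olive("correlation matrix must be symmetric")
  }
  if (any(abs(diag(correlation) - 1) > 1e-10)) {
    stop_olive("correlation matrix must have unit diagonal")
  }
  # expand to the full trait set: unspecified traits uncorrelated
  full <- diag(length(traits))
  dimnames(full) <- list(traits, traits)
  full[cn, cn] <- correlation
  nearest_pd_correlation(full)
}

# physical traits cannot go negative (and ratio coefficients live in (0, 1]);
# the Gaussian tails are clipped, affecting a ~1e-3 fraction of draws for the
# most variable cultivars
clamp_physical_traits <- function(X) {
  positive <- grep("Volume|Surface_area|Weight|Lenticel|_L_W$|Width|Height|Number_of_grooves",
                   colnames(X), value = TRUE)
  for (cn in positive) X[, cn] <- pmax(X[, cn], 1e-3)
  unit <- grep("Sphericity|Asymmetry|Flat", colnames(X), value = TRUE)
  for (cn in unit) X[, cn] <- pmin(pmax(X[, cn], 1e-3), 1)
  X
}

olive_ids <- function(varieties) {
  ave(varieties, varieties, FUN = function(v) sprintf("%s_%03d", v, seq_along(v)))
}

assign_batches <- function(profile, n) {
  b <- profile$batch_labels
  idx <- rep_len(seq_len(nrow(b)), n)
  b[idx, ]
}

#' Sample a synthetic per-olive trait table
#'
#' Draws continuous morphometric traits for each cultivar from a multivariate
#' normal with the profile's means/SDs and a shared correlation structure,
#' attaching olive ids and cycled (year, farm) batch labels so that every
#' batch cell is represented within each variety.
#'
#' @param profiles List of [variety_profile()] objects.
#' @param n_per_variety Integer vector of sample sizes (recycled against
#'   profiles; default each profile's `n_default`).
#' @param correlation Trait correlation matrix (possibly covering a subset of
#'   traits; see [default_trait_correlation()]), or `NULL` for the default.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble with `olive_id`, `variety`, `year`, `farm` and one column
#'   per trait.
#' @export
sample_trait_table <- function(profiles, n_per_variety = NULL,
                               correlation = NULL, seed = 1L) {
  if (inherits(profiles, "variety_profile")) profiles <- list(profiles)
  traits <- names(profiles[[1]]$trait_means)
  for (p in profiles) {
    if (!identical(sort(names(p$trait_means)), sort(traits))) {
      stop_olive("all profiles must share the same trait set")
    }
  }
  if (is.null(n_per_variety)) {
    n_per_variety <- vapply(profiles, function(p) p$n_default, integer(1))
  }
  n_per_variety <- rep_len(as.integer(n_per_variety), length(profiles))
  if (any(n_per_variety < 2)) stop_olive("need n >= 2 olives per variety")
  R <- check_correlation_spec(correlation, traits)
  L <- chol(R)
  with_seed(seed, {
    rows <- purrr::map2(profiles, n_per_variety, function(pf, n) {
      Z <- matrix(rnorm(n * length(traits)), n, length(traits)) %*% L
      X <- sweep(Z, 2, pf$trait_sds[traits], `*`)
      X <- sweep(X, 2, pf$trait_means[traits], `+`)
      colnames(X) <- traits
      X <- clamp_physical_traits(X)
      bind_cols(tibble(variety = pf$name), assign_batches(pf, n), as_tibble(X))
    })
    out <- bind_rows(rows)
    out <- mutate(out,
                  olive_id = olive_ids(.data$variety),
                  variety = factor(.data$variety,
                                   levels = vapply(profiles, `[[`, "", "name")),
                  .before = 1)
    out
  })
}

#' Sample visually-assessed UPOV notes
#'
#' Draws categorical notes for the six visually-assessed UPOV characteristics
#' (fruit apex/base/nipple, stone apex/base/mucron) from each profile's note
#' distributions. Rows align one-for-one (by `olive_id`) with a trait table
#' sampled with the same profiles and counts.
#'
#' @inheritParams sample_trait_table
#' @param characteristics Characteristics to draw (default the six visual ones).
#' @return A tibble with `olive_id`, `variety` and one integer note column per
#'   characteristic.
#' @export
sample_visual_notes <- function(profiles, n_per_variety = NULL, seed = 1L,
                                characteristics = VISUAL_CHARACTERISTICS) {
  if (inherits(profiles, "variety_profile")) profiles <- list(profiles)
  if (is.null(n_per_variety)) {
    n_per_variety <- vapply(profiles, function(p) p$n_default, integer(1))
  }
  n_per_variety <- rep_len(as.integer(n_per_variety), length(profiles))
  for (p in profiles) {
    missing <- setdiff(characteristics, names(p$note_freqs))
    if (length(missing)) {
      stop_olive("profile ", p$name, " lacks note frequencies for: ",
                 paste(missing, collapse = ", "))
    }
  }
  with_seed(seed + 1L, {
    rows <- purrr::map2(profiles, n_per_variety, function(pf, n) {
      notes <- lapply(characteristics, function(ch) {
        p <- pf$note_freqs[[ch]]
        codes <- as.integer(names(p))
        codes[sample.int(length(p), n, replace = TRUE, prob = p)]
      })
      names(notes) <- characteristics
      bind_cols(tibble(variety = pf$name), as_tibble(notes))
    })
    out <- bind_rows(rows)
    mutate(out,
           olive_id = olive_ids(.data$variety),
           variety = factor(.data$variety,
                            levels = vapply(profiles, `[[`, "", "name")),
           .before = 1)
  })
}
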