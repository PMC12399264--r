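#' Construct a variety profile
#'
#' A variety profile parameterizes the synthetic trait/note generator for one
#' olive cultivar: per-trait means and standard deviations of the continuous
#' morphometric traits, categorical note distributions for the UPOV
#' characteristics, a default sample size and the (year, farm) batch structure.
#'
#' @param name Cultivar name.
#' @param trait_means,trait_sds Named numeric vectors over the same trait set
#'   (see [trait_names()]); standard deviations must be non-negative.
#' @param note_freqs Named list; each element is a named numeric vector of
#'   probabilities over integer note codes (names are the codes). Distributions
#'   are renormalized to sum to one.
#' @param n_default Default number of olives to draw for this variety.
#' @param batch_labels Data frame with columns `year` and `farm` listing the
#'   harvest batches the variety was sampled from.
#' @return An object of class `variety_profile`.
#' @export
variety_profile <- function(name, trait_means, trait_sds, note_freqs,
                            n_default, batch_labels = default_batches()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!setequal(names(trait_means), names(trait_sds))) {
    stop_olive("trait_means and trait_sds must cover the same trait names")
  }
  trait_sds <- trait_sds[names(trait_means)]
  if (any(trait_sds < 0)) stop_olive("all trait standard deviations must be >= 0")
  note_freqs <- lapply(note_freqs, function(p) {
    if (any(p < 0) || sum(p) <= 0) stop_olive("note frequencies must be non-negative with positive sum")
    p / sum(p)
  })
  check_number(n_default, "n_default", lower = 2)
  stopifnot(is.data.frame(batch_labels), all(c("year", "farm") %in% names(batch_labels)))
  structure(
    list(name = name, trait_means = trait_means, trait_sds = trait_sds,
         note_freqs = note_freqs, n_default = as.integer(n_default),
         batch_labels = as_tibble(batch_labels)),
    class = "variety_profile"
  )
}

#' @export
print.variety_profile <- function(x, ...) {
  cat(sprintf("<variety_profile> %s: %d traits, %d characteristics, n_default = %d\n",
              x$name, length(x$trait_means), length(x$note_freqs), x$n_default))
  invisible(x)
}

default_batches <- function() {
  tidyr::expand_grid(year = c(2020L, 2021L), farm = c("F1", "F2"))
}

# published per-variety group sizes (order: Ravece, Ortice, Frantoio,
# Rotondella, Minucciola)
OLIVE_GROUP_N <- c(Ravece = 32L, Ortice = 27L, Frantoio = 35L,
                   Rotondella = 16L, Minucciola = 11L)

# mean and standard error of every continuous trait, one row per trait,
# one (mean, se) pair per cultivar
olive_trait_summary_raw <- function() {
  tribble_cols <- c("trait",
                    "Ravece_m", "Ravece_se", "Ortice_m", "Ortice_se",
                    "Frantoio_m", "Frantoio_se", "Rotondella_m", "Rotondella_se",
                    "Minucciola_m", "Minucciola_se")
  m <- matrix(c(
    3.62, 0.12,   3.30, 0.14,   1.82, 0.10,   2.01, 0.12,   1.78, 0.09,
    12.66, 0.34, 11.82, 0.39,   7.84, 0.29,   8.36, 0.36,   7.58, 0.22,
    0.872, 0.002, 0.870, 0.002, 0.880, 0.002, 0.889, 0.002, 0.891, 0.002,
    1.55, 0.01,   1.61, 0.02,   1.47, 0.02,   1.39, 0.03,   1.42, 0.02,
    0.58, 0.02,   0.55, 0.04,   0.76, 0.02,   0.65, 0.05,   0.76, 0.03,
    -1.32, 0.16, -1.81, 0.25,   0.29, 0.21,   0.11, 0.26,  -0.35, 0.32,
    3.47, 0.11,   3.15, 0.15,   1.76, 0.09,   1.90, 0.11,   1.74, 0.11,
    78.54, 3.57, 76.44, 4.40, 103.01, 4.73,  93.75, 5.13, 118.49, 6.14,
    0.45, 0.01,   0.46, 0.01,   0.35, 0.01,   0.33, 0.02,   0.23, 0.01,
    3.83, 0.13,   3.90, 0.12,   3.08, 0.12,   2.89, 0.13,   2.38, 0.08,
    0.743, 0.006, 0.740, 0.007, 0.787, 0.004, 0.796, 0.007, 0.774, 0.012,
    2.50, 0.03,   2.61, 0.06,   2.10, 0.03,   1.90, 0.08,   2.14, 0.05,
    0.39, 0.03,   0.33, 0.03,   0.51, 0.02,   0.46, 0.05,   0.37, 0.03,
    -0.25, 0.36, -1.24, 0.35,  -1.22, 0.38,   0.66, 0.63,  -1.01, 1.02,
    0.48, 0.02,   0.48, 0.01,   0.38, 0.02,   0.35, 0.02,   0.24, 0.00,
    3.75, 0.31,   3.67, 0.37,   2.40, 0.21,   3.88, 0.55,   2.09, 0.28,
    100.02, 4.06, 88.92, 4.01, 72.77, 3.89,  69.67, 6.62,  59.44, 3.94,
    134.33, 3.98, 124.15, 3.92, 105.83, 4.76, 98.50, 5.90,  90.57, 3.78,
    4.92, 0.08,   4.68, 0.08,   4.45, 0.11,   4.76, 0.21,   4.09, 0.11,
    0.77, 0.00,   0.77, 0.00,   0.79, 0.00,   0.81, 0.01,   0.80, 0.00,
    3.84, 0.05,   3.56, 0.08,   3.41, 0.07,   3.54, 0.15,   3.35, 0.85,
    3.18, 0.06,   3.50, 0.09,   3.07, 0.08,   2.61, 0.13,   2.79, 0.09,
    0.78, 0.00,   0.76, 0.01,   0.77, 0.01,   0.74, 0.01,   0.82, 0.01,
    0.64, 0.34,   0.10, 0.32,   0.12, 0.25,   0.69, 0.38,   0.00, 0.54
  ), ncol = 10, byrow = TRUE)
  out <- as_tibble(as.data.frame(m))
  names(out) <- tribble_cols[-1]
  out$trait <- OLIVE_TRAITS
  out[, tribble_cols]
}

#' Published per-variety trait summary
#'
#' Group means, standard errors and sample sizes of the 24 continuous
#' morphometric traits for the five Campania cultivars, in long tidy form.
#' These summaries parameterize the default synthetic generator and the
#' summary-mode Tukey analysis.
#'
#' @return A tibble with columns `trait`, `variety`, `mean`, `se`, `n`.
#' @export
olive_trait_summary <- function() {
  raw <- olive_trait_summary_raw()
  out <- purrr::map_dfr(names(OLIVE_GROUP_N), function(v) {
    tibble(trait = raw$trait, variety = v,
           mean = raw[[paste0(v, "_m")]], se = raw[[paste0(v, "_se")]],
           n = OLIVE_GROUP_N[[v]])
  })
  out$variety <- factor(out$variety, levels = names(OLIVE_GROUP_N))
  out
}

# percent of olives per state of expression for every UPOV characteristic;
# integer note codes as published (irregular across characteristics)
olive_note_freq_raw <- function() {
  f <- function(notes, R, O, Fr, Ro, M) {
    list(notes = notes,
         Ravece = R, Ortice = O, Frantoio = Fr, Rotondella = Ro, Minucciola = M)
  }
  list(
    # computationally derived characteristics
    D_Shape            = f(c(1, 2, 4, 5, 6),
                           c(3, 91, 6, 0, 0), c(11, 81, 7, 0, 0),
                           c(3, 60, 37, 0, 0), c(6, 25, 63, 0, 6), c(0, 36, 64, 0, 0)),
    D_L_W              = f(c(3, 5, 7),
                           c(0, 9, 91), c(0, 19, 81), c(0, 40, 60),
                           c(0, 75, 25), c(0, 64, 36)),
    D_Symmetry         = f(1:3,
                           c(9, 59, 31), c(15, 44, 41), c(46, 46, 9),
                           c(25, 50, 25), c(27, 73, 0)),
    D_Weight           = f(c(1, 3, 5, 7, 9),
                           c(0, 0, 88, 13, 0), c(0, 0, 85, 15, 0),
                           c(0, 80, 20, 0, 0), c(0, 75, 25, 0, 0), c(0, 64, 36, 0, 0)),
    D_Lenticels_number = f(1:3,
                           c(0, 28, 72), c(0, 41, 59), c(0, 14, 86),
                           c(0, 6, 94), c(0, 0, 100)),
    E_Shape            = f(1:5,
                           c(3, 94, 3, 0, 0), c(0, 85, 11, 0, 4),
                           c(29, 29, 34, 0, 9), c(13, 13, 44, 0, 31),
                           c(36, 36, 0, 0, 27)),
    E_L_W              = f(1:3,
                           c(0, 6, 94), c(0, 15, 85), c(0, 71, 29),
                           c(0, 88, 13), c(0, 64, 36)),
    E_Symmetry         = f(1:3,
                           c(0, 28, 72), c(4, 11, 85), c(0, 49, 51),
                           c(6, 31, 63), c(0, 18, 82)),
    E_Weight           = f(c(1, 3, 5, 7, 9),
                           c(0, 6, 19, 75, 0), c(0, 4, 30, 67, 0),
                           c(0, 20, 54, 26, 0), c(0, 31, 56, 13, 0),
                           c(0, 100, 0, 0, 0)),
    E_Rugosity         = f(1:3,
                           c(56, 34, 9), c(48, 41, 11), c(83, 17, 0),
                           c(50, 38, 13), c(100, 0, 0)),
    # visually assessed characteristics
    D_Apex             = f(1:3,
                           c(72, 28, 0), c(67, 22, 11), c(3, 40, 57),
                           c(19, 31, 50), c(18, 64, 18)),
    D_Base             = f(1:3,
                           c(0, 0, 100), c(0, 0, 100), c(9, 0, 91),
                           c(19, 0, 81), c(45, 0, 55)),
    D_Nipple           = f(1:3,
                           c(63, 31, 6), c(78, 22, 0), c(91, 9, 0),
                           c(100, 0, 0), c(82, 18, 0)),
    E_Apex             = f(1:3,
                           c(81, 19, 0), c(89, 11, 0), c(0, 100, 0),
                           c(6, 94, 0), c(27, 73, 0)),
    E_Base             = f(1:3,
                           c(72, 28, 0), c(89, 11, 0), c(49, 49, 3),
                           c(19, 69, 13), c(45, 36, 18)),
    E_Mucron           = f(c(1, 9),
                           c(16, 84), c(0, 100), c(6, 94), c(19, 81), c(9, 91))
  )
}

#' Published UPOV note frequencies
#'
#' Per-variety categorical distributions over the states of expression of the
#' 16 UPOV characteristics (10 derived from morphometric traits, 6 visually
#' assessed), in long tidy form. Percentages are renormalized to proportions
#' summing to one within each (characteristic, variety).
#'
#' @return A tibble with columns `characteristic`, `provenance`, `note`,
#'   `variety`, `freq`.
#' @export
olive_note_summary <- function() {
  raw <- olive_note_freq_raw()
  out <- purrr::map_dfr(names(raw), function(ch) {
    rec <- raw[[ch]]
    purrr::map_dfr(names(OLIVE_GROUP_N), function(v) {
      p <- rec[[v]]
      tibble(characteristic = ch,
             provenance = ifelse(ch %in% VISUAL_CHARACTERISTICS, "visual", "derived"),
             note = rec$notes, variety = v, freq = p / sum(p))
    })
  })
  out$variety <- factor(out$variety, levels = names(OLIVE_GROUP_N))
  out
}

#' Default variety profiles for the five Campania cultivars
#'
#' Builds one [variety_profile()] per cultivar (Ravece, Ortice, Frantoio,
#' Rotondella, Minucciola) from the published per-variety trait summaries and
#' UPOV note frequencies. Standard deviations are reconstructed from the
#' printed standard errors as `SE * sqrt(n)` with the published group sizes
#' (32, 27, 35, 16, 11).
#'
#' @return Named list of five `variety_profile` objects.
#' @examples
#' p <- build_default_profiles()
#' p$Ravece$trait_means[["D_Volume"]]  # 3.62 cm^3
#' @export
build_default_profiles <- function() {
  ts <- olive_trait_summary()
  ns <- olive_note_summary()
  profiles <- lapply(names(OLIVE_GROUP_N), function(v) {
    tv <- ts[ts$variety == v, ]
    means <- setNames(tv$mean, tv$trait)
    sds   <- setNames(tv$se * sqrt(tv$n), tv$trait)
    nf <- lapply(split(ns[ns$variety == v, ], ns$characteristic[ns$variety == v]),
                 function(d) setNames(d$freq, d$note))
    variety_profile(v, means, sds, nf, n_default = OLIVE_GROUP_N[[v]])
  })
  setNames(profiles, names(OLIVE_GROUP_N))
}
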