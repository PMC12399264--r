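toy_traits <- function(...) {
  defaults <- list(olive_id = "o1", D_L_W = 1.3, D_Position_of_MTA = 0,
                   D_Asymmetry_coefficient = 0.6, D_Weight = 2.5,
                   D_Lenticel_density = 50, E_L_W = 2.0,
                   E_Position_of_MTA = 0, E_Asymmetry_coefficient = 0.6,
                   E_Weight = 0.4, E_Rugosity_index = 1.08)
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

test_that("ordered characteristics map through the default breakpoints", {
  n <- derive_notes(toy_traits(D_Weight = 1.76))
  expect_equal(n$D_Weight, 3L)     # "Low" under breaks 1/2/4/6 g
  n2 <- derive_notes(toy_traits(D_L_W = 1.61))
  expect_equal(n2$D_L_W, 7L)       # "Very elongated"
  # boundary values go to the upper class
  n3 <- derive_notes(toy_traits(D_Weight = 2))
  expect_equal(n3$D_Weight, 5L)
  # negative trait -> representable-range error
  expect_error(derive_notes(toy_traits(D_Weight = -1)), "representable")
})

test_that("shape notes combine elongation with the MTA sign", {
  expect_equal(derive_notes(toy_traits(D_L_W = 1.5, D_Position_of_MTA = -6))$D_Shape,
               1L)  # ovate
  expect_equal(derive_notes(toy_traits(D_L_W = 1.5, D_Position_of_MTA = 6))$D_Shape,
               6L)  # obovate
  expect_equal(derive_notes(toy_traits(D_L_W = 1.6, D_Position_of_MTA = 0))$D_Shape,
               2L)  # oblong
  expect_equal(derive_notes(toy_traits(D_L_W = 1.3, D_Position_of_MTA = 0))$D_Shape,
               4L)  # elliptic
  expect_equal(derive_notes(toy_traits(D_L_W = 1.05, D_Position_of_MTA = 0))$D_Shape,
               5L)  # circular
})

test_that("ordinal notes are monotone in the underlying trait", {
  th <- default_note_thresholds()
  inc <- c(D_L_W = "D_L_W", D_Weight = "D_Weight",
           D_Lenticels_number = "D_Lenticel_density", E_L_W = "E_L_W",
           E_Weight = "E_Weight", E_Rugosity = "E_Rugosity_index")
  for (ch in names(inc)) {
    grid <- seq(0.01, 10, length.out = 120)
    tt <- do.call(toy_traits, setNames(list(grid), inc[[ch]]))
    tt$olive_id <- sprintf("o%03d", seq_along(grid))
    notes <- derive_notes(tt, th)[[ch]]
    expect_true(all(diff(notes) >= 0), info = ch)
  }
  # symmetry notes decrease as the symmetry coefficient increases
  grid <- seq(0.05, 0.99, length.out = 60)
  tt <- toy_traits(D_Asymmetry_coefficient = grid,
                   E_Asymmetry_coefficient = grid)
  tt$olive_id <- sprintf("o%03d", seq_along(grid))
  nn <- derive_notes(tt, th)
  expect_true(all(diff(nn$D_Symmetry) <= 0))
  expect_true(all(diff(nn$E_Symmetry) <= 0))
})

test_that("published variety means map to the published modal notes", {
  ts <- olive_trait_summary()
  ns <- olive_note_summary()
  wide <- tidyr::pivot_wider(ts[c("trait", "variety", "mean")],
                             names_from = "trait", values_from = "mean")
  wide$olive_id <- as.character(wide$variety)
  derived <- derive_notes(wide)
  ordered_chars <- c("D_L_W", "D_Symmetry", "D_Weight", "D_Lenticels_number",
                     "E_L_W", "E_Symmetry", "E_Weight")
  for (ch in ordered_chars) {
    for (v in levels(ns$variety)) {
      d <- ns[ns$characteristic == ch & ns$variety == v, ]
      modal <- d$note[d$freq == max(d$freq)]  # ties allow either mode
      expect_true(derived[[ch]][derived$olive_id == v] %in% modal,
                  info = paste(ch, v))
    }
  }
})

test_that("note tables merge disjointly and preserve provenance", {
  p <- build_default_profiles()
  tt <- sample_trait_table(p, seed = 2)
  tt$E_Rugosity_index <- 1.08  # imaging-derived trait absent from sampling
  derived <- derive_notes(tt)
  visual <- sample_visual_notes(p, seed = 2)
  merged <- merge_visual_notes(derived, visual)
  chars <- setdiff(names(merged), c("olive_id", "variety", "year", "farm"))
  expect_length(chars, 16)
  expect_equal(nrow(merged), 121)
  prov <- attr(merged, "provenance")
  expect_equal(sum(prov == "visual"), 6)
  expect_equal(sum(prov == "derived"), 10)
  # overlapping characteristic -> error
  clash <- visual
  clash$D_Weight <- 1L
  expect_error(merge_visual_notes(derived, clash), "duplicate characteristic")
  # mismatched ids -> error
  expect_error(merge_visual_notes(derived, visual[-1, ]), "mismatched")
})
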