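# internal helpers shared across modules

# canonical trait column order (fruit D, stone E, cavity C)
OLIVE_TRAITS <- c(
  "D_Volume", "D_Surface_area", "D_Sphericity", "D_L_W",
  "D_Asymmetry_coefficient", "D_Position_of_MTA", "D_Weight",
  "D_Lenticel_density",
  "E_Volume", "E_Surface_area", "E_Sphericity", "E_L_W",
  "E_Asymmetry_coefficient", "E_Position_of_MTA", "E_Weight",
  "E_Number_of_grooves",
  "C_Volume", "C_Surface_area", "C_Width", "C_Sphericity", "C_Height",
  "C_L_W", "C_Flat", "C_Position_of_MTA"
)

VISUAL_CHARACTERISTICS  <- c("D_Apex", "D_Base", "D_Nipple",
                             "E_Apex", "E_Base", "E_Mucron")
DERIVED_CHARACTERISTICS <- c("D_Shape", "D_L_W", "D_Symmetry", "D_Weight",
                             "D_Lenticels_number", "E_Shape", "E_L_W",
                             "E_Symmetry", "E_Weight", "E_Rugosity")

#' Trait names of an object subset
#'
#' Selects the canonical trait (and optionally note) columns belonging to the
#' requested drupe compartments: `"D"` whole fruit, `"E"` stone, `"C"` stone
#' cavity.
#'
#' @param objects Character vector, subset of `c("D", "E", "C")`.
#' @param notes If `TRUE`, also return the visual UPOV characteristics of the
#'   selected compartments (the cavity has none).
#' @return Character vector of column names.
#' @export
trait_names <- function(objects = c("D", "E", "C"), notes = FALSE) {
  objects <- match.arg(objects, several.ok = TRUE)
  keep <- OLIVE_TRAITS[substr(OLIVE_TRAITS, 1, 1) %in% objects]
  if (notes) {
    keep <- c(keep,
              VISUAL_CHARACTERISTICS[substr(VISUAL_CHARACTERISTICS, 1, 1) %in% objects])
  }
  keep
}

stop_olive <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_olive(sprintf("`%s` must be a number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
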