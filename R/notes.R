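#' Default note thresholds
#'
#' Breakpoints mapping continuous traits to UPOV states of expression for the
#' characteristics that are derived computationally. Values are engineering
#' calibration chosen so that each cultivar's published trait mean maps to its
#' published modal note; every breakpoint is user-overridable. Boundary values
#' fall in the upper class.
#'
#' Ordered characteristics are plain interval maps. The two shape
#' characteristics combine the elongation class with the signed position of
#' the maximum transverse area (MTA): clearly below mid-body (ovate), clearly
#' above (obovate), otherwise oblong/elliptic/circular by elongation.
#'
#' @return Named list of threshold specifications.
#' @export
default_note_thresholds <- function() {
  ordered_spec <- function(trait, breaks, notes) {
    list(kind = "ordered", trait = trait, breaks = breaks, notes = notes)
  }
  shape_spec <- function(lw_trait, mta_trait, notes, mta_tol, circular_break,
                         oblong_break) {
    # notes: c(ovate, oblong, elliptic, circular, obovate)
    list(kind = "shape", lw_trait = lw_trait, mta_trait = mta_trait,
         notes = notes, mta_tol = mta_tol, circular_break = circular_break,
         oblong_break = oblong_break)
  }
  list(
    D_Shape = shape_spec("D_L_W", "D_Position_of_MTA",
                         notes = c(ovate = 1, oblong = 2, elliptic = 4,
                                   circular = 5, obovate = 6),
                         mta_tol = 2, circular_break = 1.1, oblong_break = 1.45),
    D_L_W = ordered_spec("D_L_W", breaks = c(1.25, 1.45), notes = c(3, 5, 7)),
    D_Symmetry = ordered_spec("D_Asymmetry_coefficient",
                              breaks = c(0.55, 0.78), notes = c(3, 2, 1)),
    D_Weight = ordered_spec("D_Weight", breaks = c(1, 2, 4, 6),
                            notes = c(1, 3, 5, 7, 9)),
    D_Lenticels_number = ordered_spec("D_Lenticel_density", breaks = c(30, 70),
                                      notes = c(1, 2, 3)),
    E_Shape = shape_spec("E_L_W", "E_Position_of_MTA",
                         notes = c(ovate = 1, oblong = 2, elliptic = 3,
                                   circular = 4, obovate = 5),
                         mta_tol = 2, circular_break = 1.2, oblong_break = 2.2),
    E_L_W = ordered_spec("E_L_W", breaks = c(1.8, 2.2), notes = c(1, 2, 3)),
    E_Symmetry = ordered_spec("E_Asymmetry_coefficient",
                              breaks = c(0.52, 0.7), notes = c(3, 2, 1)),
    E_Weight = ordered_spec("E_Weight", breaks = c(0.2, 0.3, 0.45, 0.7),
                            notes = c(1, 3, 5, 7, 9)),
    E_Rugosity = ordered_spec("E_Rugosity_index", breaks = c(1.05, 1.12),
                              notes = c(1, 2, 3))
  )
}

map_ordered_note <- function(x, breaks, notes) {
  if (any(!is.finite(x))) stop_olive("non-finite trait value in note derivation")
  notes[findInterval(x, breaks) + 1L]  # boundary value -> upper class
}

map_shape_note <- function(lw, mta, sp) {
  if (any(!is.finite(lw)) || any(!is.finite(mta))) {
    stop_olive("non-finite trait value in shape note derivation")
  }
  out <- integer(length(lw))
  out[mta < -sp$mta_tol] <- sp$notes[["ovate"]]
  out[mta > sp$mta_tol] <- sp$notes[["obovate"]]
  mid <- out == 0L
  out[mid & lw < sp$circular_break] <- sp$notes[["circular"]]
  out[mid & lw >= sp$oblong_break] <- sp$notes[["oblong"]]
  out[out == 0L] <- sp$notes[["elliptic"]]
  out
}

#' Derive UPOV notes from continuous traits
#'
#' Deterministically discretizes the trait columns of a trait table into the
#' computationally-derived UPOV characteristics under the given thresholds.
#' Characteristics whose underlying trait column is absent (e.g. the rugosity
#' index on tables without imaging) are skipped.
#'
#' @param traits Trait table (tibble with trait columns; id columns carried
#'   through).
#' @param thresholds Threshold set, see [default_note_thresholds()].
#' @return Tibble with the id columns of `traits` plus one integer note
#'   column per derivable characteristic; the `provenance` attribute maps
#'   characteristic to `"derived"`.
#' @export
derive_notes <- function(traits, thresholds = default_note_thresholds()) {
  nonneg <- intersect(c("D_Weight", "E_Weight", "D_Lenticel_density",
                        "D_L_W", "E_L_W", "E_Rugosity_index",
                        "D_Volume", "E_Volume"),
                      names(traits))
  for (cn in nonneg) {
    if (any(traits[[cn]] < 0, na.rm = TRUE)) {
      stop_olive("trait outside representable range: negative ", cn)
    }
  }
  id_cols <- intersect(c("olive_id", "variety", "year", "farm"), names(traits))
  out <- traits[id_cols]
  for (ch in names(thresholds)) {
    sp <- thresholds[[ch]]
    if (sp$kind == "ordered") {
      if (!sp$trait %in% names(traits)) next
      if (is.unsorted(sp$breaks, strictly = TRUE)) {
        stop_olive("breakpoints for ", ch, " must be strictly increasing")
      }
      out[[ch]] <- as.integer(map_ordered_note(traits[[sp$trait]],
                                               sp$breaks, sp$notes))
    } else {
      if (!all(c(sp$lw_trait, sp$mta_trait) %in% names(traits))) next
      out[[ch]] <- as.integer(map_shape_note(traits[[sp$lw_trait]],
                                             traits[[sp$mta_trait]], sp))
    }
  }
  derived <- setdiff(names(out), id_cols)
  attr(out, "provenance") <- setNames(rep("derived", length(derived)), derived)
  out
}

#' Merge derived and visually-assessed note tables
#'
#' Joins two note tables row-for-row by `olive_id`. The characteristic sets
#' must be disjoint; provenance flags are preserved.
#'
#' @param derived,visual Note tables (tibbles with `olive_id` plus note
#'   columns).
#' @return Combined note table with a `provenance` attribute.
#' @export
merge_visual_notes <- function(derived, visual) {
  id_cols_d <- intersect(c("olive_id", "variety", "year", "farm"), names(derived))
  id_cols_v <- intersect(c("olive_id", "variety", "year", "farm"), names(visual))
  chars_d <- setdiff(names(derived), id_cols_d)
  chars_v <- setdiff(names(visual), id_cols_v)
  dup <- intersect(chars_d, chars_v)
  if (length(dup)) {
    stop_olive("duplicate characteristic(s) in merge: ", paste(dup, collapse = ", "))
  }
  if (!setequal(derived$olive_id, visual$olive_id)) {
    stop_olive("mismatched olive ids between note tables")
  }
  out <- left_join(derived, visual[c("olive_id", chars_v)], by = "olive_id")
  prov_d <- attr(derived, "provenance") %||%
    setNames(rep("derived", length(chars_d)), chars_d)
  prov_v <- attr(visual, "provenance") %||%
    setNames(rep("visual", length(chars_v)), chars_v)
  attr(out, "provenance") <- c(prov_d, prov_v)
  out
}
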