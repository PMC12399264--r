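#' Build and validate a pipeline run configuration
#'
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory for CSVs and the JSON run report
#'   (`NULL` = return results only).
#' @param n_per_variety Olives per variety (`NULL` = published group sizes).
#' @param correlation Trait correlation override (see
#'   [default_trait_correlation()]).
#' @param predictor_mode `"traits+visual"` (default), `"traits"` or
#'   `"notes"` (derived + visual notes only).
#' @param combinations Named list of compartment combinations analysed by
#'   LDA/overlap; default all of D+E+C, D+E, D, E, C.
#' @param note_thresholds Note threshold set.
#' @param svm_ratio,svm_cost Train fraction and soft-margin cost of the SVM
#'   stage.
#' @param volumetric If `TRUE`, also generate + segment + measure
#'   `n_volumetric` phantom olives per variety (slow path).
#' @param n_volumetric,voxel_size_um Volumetric-path sample size and voxel
#'   size.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, n_per_variety = NULL,
                       correlation = NULL,
                       predictor_mode = c("traits+visual", "traits", "notes"),
                       combinations = list("D+E+C" = c("D", "E", "C"),
                                           "D+E" = c("D", "E"),
                                           "D" = "D", "E" = "E", "C" = "C"),
                       note_thresholds = default_note_thresholds(),
                       svm_ratio = 0.7, svm_cost = 1,
                       volumetric = FALSE, n_volumetric = 2L,
                       voxel_size_um = 250) {
  predictor_mode <- match.arg(predictor_mode)
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              n_per_variety = n_per_variety, correlation = correlation,
              predictor_mode = predictor_mode, combinations = combinations,
              note_thresholds = note_thresholds,
              svm_ratio = svm_ratio, svm_cost = svm_cost,
              volumetric = isTRUE(volumetric),
              n_volumetric = as.integer(n_volumetric),
              voxel_size_um = voxel_size_um)
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param config A candidate configuration list.
#' @export
validate_run_config <- function(config) {
  check_number(config$seed, "seed")
  check_number(config$svm_ratio, "svm_ratio", lower = 1e-9, upper = 1 - 1e-9)
  check_number(config$svm_cost, "svm_cost", lower = 1e-12)
  check_number(config$voxel_size_um, "voxel_size_um", lower = 1)
  for (nm in names(config$combinations)) {
    if (!all(config$combinations[[nm]] %in% c("D", "E", "C"))) {
      stop_olive("combination ", nm, " must be a subset of D, E, C")
    }
  }
  for (ch in names(config$note_thresholds)) {
    sp <- config$note_thresholds[[ch]]
    if (identical(sp$kind, "ordered") &&
        is.unsorted(sp$breaks, strictly = TRUE)) {
      stop_olive("note thresholds for ", ch, " are not strictly increasing")
    }
  }
  structure(config, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML file override [run_config()] defaults.
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- intersect(names(raw),
                     c("seed", "out_dir", "n_per_variety", "predictor_mode",
                       "svm_ratio", "svm_cost", "volumetric", "n_volumetric",
                       "voxel_size_um"))
  do.call(run_config, raw[known])
}

combo_predictors <- function(objects, mode) {
  tr <- trait_names(objects)
  vis <- VISUAL_CHARACTERISTICS[substr(VISUAL_CHARACTERISTICS, 1, 1) %in% objects]
  switch(mode,
         "traits" = tr,
         "traits+visual" = c(tr, vis),
         "notes" = c(DERIVED_CHARACTERISTICS[substr(DERIVED_CHARACTERISTICS, 1, 1)
                                             %in% objects], vis))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, under one seed: profile construction, trait/note sampling,
#' note derivation and merging, the univariate battery (Tukey pair counts,
#' Pearson correlations, Mahalanobis screen), canonical LDA with
#' resubstitution and leave-one-out classification, Bhattacharyya overlap and
#' potency ranking for each compartment combination, and the stratified-split
#' linear-SVM prediction stage. Optionally also the volumetric path
#' (phantom generation, segmentation, trait extraction) on a small batch.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return An `olive_run` list: tables, fitted objects, confusions, overlap
#'   matrices, potency ranking, and a serializable `report`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  t_all <- proc.time()[3]
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(force(expr), error = function(e) {
      stop_olive(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[3] - t0, 3)
    res
  }

  profiles <- stage("profiles", build_default_profiles())
  traits <- stage("simulate_traits",
                  sample_trait_table(profiles, config$n_per_variety,
                                     config$correlation, seed = config$seed))
  visual <- stage("simulate_notes",
                  sample_visual_notes(profiles, config$n_per_variety,
                                      seed = config$seed))
  derived <- stage("derive_notes", derive_notes(traits, config$note_thresholds))
  notes <- stage("merge_notes", merge_visual_notes(derived, visual))
  # analysis table: trait columns plus visual notes (derived notes re-use
  # trait names, so notes-only mode analyses the note table instead)
  full <- switch(config$predictor_mode,
                 "traits" = traits,
                 "traits+visual" = left_join(
                   traits, visual[c("olive_id", VISUAL_CHARACTERISTICS)],
                   by = "olive_id"),
                 "notes" = notes)

  tukey <- stage("univariate_tukey", tukey_trait_battery(traits))
  pearson <- stage("univariate_pearson", pearson_matrix(traits, trait_names()))
  mahal <- stage("univariate_mahalanobis",
                 mahalanobis_screen(traits, trait_names()))

  combos <- config$combinations
  combos <- combos[vapply(combos, function(objs) {
    length(intersect(combo_predictors(objs, config$predictor_mode),
                     names(full))) >= 2
  }, TRUE)]
  lda_results <- stage("lda", {
    lapply(combos, function(objs) {
      preds <- intersect(combo_predictors(objs, config$predictor_mode),
                         names(full))
      fit <- fit_lda(full, preds)
      cls <- classify(fit)
      cv <- loocv(full, preds)
      ov <- bhattacharyya(fit)
      list(objects = objs, predictors = preds, fit = fit,
           confusion = cls$confusion, loocv = cv, overlap = ov)
    })
  })
  potency <- stage("potency", potency_index(lda_results[[1]]$fit))

  svm_res <- stage("svm", {
    plan <- stratified_split(full, ratio = config$svm_ratio,
                             seed = config$seed)
    full2 <- left_join(full, plan[c("olive_id", "role")], by = "olive_id")
    preds <- intersect(combo_predictors(c("D", "E", "C"), config$predictor_mode),
                       names(full2))
    model <- train_linear_svm(filter(full2, .data$role == "train"), preds,
                              cost = config$svm_cost)
    eval <- evaluate_svm(model, filter(full2, .data$role == "validation"))
    list(plan = plan, model = model, evaluation = eval)
  })

  volumetric <- NULL
  if (config$volumetric) {
    volumetric <- stage("volumetric", {
      run_volumetric_batch(profiles, config$n_volumetric,
                           config$voxel_size_um, config$seed)
    })
  }

  report <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("olivemorph")),
    n_olives = nrow(full),
    predictor_mode = config$predictor_mode,
    tukey_pairs = setNames(as.list(tukey$n_significant), tukey$trait),
    n_outliers = sum(mahal$outlier),
    lda = lapply(lda_results, function(r) {
      list(overall = r$confusion$overall, loocv = r$loocv$overall,
           average_BhC = r$overlap$average_BhC,
           eigenvalues = unname(r$fit$eigenvalues))
    }),
    top_predictors = head(potency$predictor, 5),
    svm = list(train_accuracy = svm_res$model$train_accuracy,
               validation_accuracy = svm_res$evaluation$overall),
    timings = timings
  )

  out <- structure(
    list(config = config, trait_table = traits, note_table = notes,
         tukey = tukey, pearson = pearson, mahalanobis = mahal,
         lda = lda_results, potency = potency, svm = svm_res,
         volumetric = volumetric, report = report),
    class = "olive_run"
  )
  if (!is.null(config$out_dir)) write_run_outputs(out, config$out_dir)
  report$timings$total <- round(proc.time()[3] - t_all, 3)
  out$report <- report
  out
}

#' @export
print.olive_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<olive_run> seed %d, %d olives\n", r$seed, r$n_olives))
  cat(sprintf("  LDA overall: %s%%\n",
              paste(sprintf("%s %.1f", names(r$lda),
                            vapply(r$lda, `[[`, 0, "overall")), collapse = ", ")))
  cat(sprintf("  SVM train %.1f%% / validation %.1f%%\n",
              r$svm$train_accuracy, r$svm$validation_accuracy))
  invisible(x)
}

# volumetric fast-batch: one phantom spec per variety scaled from its profile
phantom_spec_for_profile <- function(profile, seed = 1L, voxel_size_um = 250,
                                     lenticel_count = 40L) {
  m <- profile$trait_means
  fr_a <- (3 * m[["D_Volume"]] * 1000 / (4 * pi * m[["D_L_W"]]))^(1 / 3)
  st_a <- (3 * m[["E_Volume"]] * 1000 / (4 * pi * m[["E_L_W"]]))^(1 / 3)
  sc <- (m[["C_Volume"]] / (m[["E_Volume"]] * 1000))^(1 / 3)
  phantom_spec(
    fruit_semi_axes = c(fr_a, 0.96 * fr_a, fr_a * m[["D_L_W"]]),
    stone_semi_axes = c(st_a, 0.94 * st_a, st_a * m[["E_L_W"]]),
    cavity_scale = c(sc / 1.1, sc / 1.25, min(0.9, sc * 1.35)),
    groove_count = max(0L, as.integer(round(m[["E_Number_of_grooves"]]))),
    groove_depth = 0.05,
    mta_offset = m[["D_Position_of_MTA"]],
    lenticel_count = lenticel_count,
    voxel_size = voxel_size_um, seed = seed
  )
}

run_volumetric_batch <- function(profiles, n_each = 2L, voxel_size_um = 250,
                                 seed = 1L) {
  rows <- list()
  for (pf in profiles) {
    for (i in seq_len(n_each)) {
      sp <- phantom_spec_for_profile(pf, seed = seed + 1000L * i +
                                       match(pf$name, names(profiles)),
                                     voxel_size_um = voxel_size_um)
      ph <- generate_drupe_phantom(sp)
      masks <- segment_drupe(ph$volume)
      row <- measure_olive(ph$volume, masks,
                           olive_id = sprintf("%s_vol_%02d", pf$name, i),
                           asymmetry_step_deg = 3)
      row$variety <- pf$name
      rows[[length(rows) + 1]] <- row
    }
  }
  bind_rows(rows)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  w(run$trait_table, "trait_table.csv")
  w(run$note_table, "note_table.csv")
  w(run$tukey, "tukey_pair_counts.csv")
  w(tidy(run$pearson), "pearson.csv")
  w(select(run$mahalanobis, all_of(c("olive_id", "variety", "md2", "outlier"))),
    "mahalanobis.csv")
  for (nm in names(run$lda)) {
    safe <- gsub("[^A-Za-z]", "", nm)
    w(as.data.frame(run$lda[[nm]]$confusion$counts),
      sprintf("lda_confusion_%s.csv", safe))
    w(run$lda[[nm]]$overlap$pairs, sprintf("bhattacharyya_%s.csv", safe))
  }
  w(run$potency, "potency_ranking.csv")
  w(run$svm$plan, "split_plan.csv")
  w(as.data.frame(run$svm$evaluation$confusion$counts), "svm_confusion.csv")
  if (!is.null(run$volumetric)) w(run$volumetric, "volumetric_traits.csv")
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
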