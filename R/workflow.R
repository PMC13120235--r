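#' Qualitative + quantitative workflow for one targeted variety
#'
#' Reproduces the per-variety analysis shape: a binary PLS-DA model built
#' on the subset-design samples (label: variety proportion > 0) with a
#' duplex-selected external test set and the six-pre-treatment sweep; a
#' limit of detection from the variety's trituration series; and a PLS1
#' regression of the variety proportion on the positive samples only
#' (subset rows containing the variety plus its targeted triturations),
#' with its own independent duplex split and sweep. Duplex distances are
#' always computed on the raw (un-pre-treated) spectra.
#'
#' @param spectra a [spectra_set()] covering the full design (region-cut
#'   already if MID-IR).
#' @param composition the matching [composition_table()]; its `design`
#'   data.frame (labels `pure`..`senary`, `trituration` + `target`)
#'   determines which rows enter classification, regression and LOD.
#' @param variety targeted variety name.
#' @param seed integer seed driving the CV fold assignments.
#' @param test_fraction external test-set fraction (default 0.2; the test
#'   size is `round(test_fraction * n)`).
#' @param max_lv,folds,specs passed to [sweep_pretreatments()].
#' @return an object of class `variety_workflow`: `variety`,
#'   `classification` and `regression` (both `selection_report`s), `lod`
#'   (an `lod_result`), and the two `split_result`s.
#' @export
run_variety_workflow <- function(spectra, composition, variety, seed,
                                 test_fraction = 0.2, max_lv = 15L,
                                 folds = 10L,
                                 specs = default_pretreatments()) {
  if (!variety %in% composition$varieties) {
    stop("variety '", variety, "' not present in the composition table")
  }
  des <- composition$design
  if (is.null(des)) {
    stop("composition table carries no design labels; build it with ",
         "build_mixture_design()/build_trituration_design()")
  }
  prop <- composition$proportions[, variety]
  is_trit <- des$label == "trituration"

  # qualitative branch: subset-design samples only
  cls_idx <- which(!is_trit)
  cls_x <- subset_samples(spectra, cls_idx)
  cls_y <- prop[cls_idx] > 0
  cls_split <- duplex_split(cls_x, round(test_fraction * length(cls_idx)))
  cls_report <- sweep_pretreatments(
    subset_samples(cls_x, cls_split$train_indices),
    subset_samples(cls_x, cls_split$test_indices),
    cls_y[cls_split$train_indices], cls_y[cls_split$test_indices],
    task = "classification", specs = specs, max_lv = max_lv,
    folds = folds, seed = seed, positive_label = variety
  )

  # LOD from this variety's trituration series, ascending level order
  trit_idx <- which(is_trit & des$target == variety)
  trit_idx <- trit_idx[order(prop[trit_idx])]
  lod <- estimate_lod(cls_report$chosen_model, cls_report$chosen_fitted,
                      subset_samples(spectra, trit_idx),
                      levels = unname(prop[trit_idx]), variety = variety)

  # quantitative branch: positives (subset rows + targeted triturations)
  reg_idx <- which((!is_trit & prop > 0) |
                     (is_trit & des$target == variety))
  reg_x <- subset_samples(spectra, reg_idx)
  reg_y <- prop[reg_idx]
  reg_split <- duplex_split(reg_x, round(test_fraction * length(reg_idx)))
  reg_report <- sweep_pretreatments(
    subset_samples(reg_x, reg_split$train_indices),
    subset_samples(reg_x, reg_split$test_indices),
    reg_y[reg_split$train_indices], reg_y[reg_split$test_indices],
    task = "regression", specs = specs, max_lv = max_lv,
    folds = folds, seed = seed
  )

  structure(
    list(variety = variety,
         classification = cls_report, regression = reg_report, lod = lod,
         classification_split = cls_split, regression_split = reg_split,
         classification_indices = cls_idx, regression_indices = reg_idx),
    class = "variety_workflow"
  )
}

#' Screen unknown samples with the selected per-variety models
#'
#' For every sample and variety, the qualitative (PLS-DA) model is applied
#' first; the quantitative model is applied only when the qualitative flag
#' is positive. Estimates below the lowest calibrated proportion carry a
#' below-calibration marker while the raw value (possibly negative) is
#' retained.
#'
#' @param models named list (one element per variety) of lists with
#'   components `da` (a `da_model`), `da_fitted`, `reg` (a `pls_model`) and
#'   `reg_fitted`.
#' @param unknowns a [spectra_set()] of the samples to screen, on the same
#'   raw grid the models were trained on.
#' @param calibration_min lowest calibrated proportion in percent
#'   (default 1).
#' @return an object of class `screening_report`: a long data.frame
#'   (`sample_id`, `variety`, `positive`, `estimate`,
#'   `below_calibration`, `display`) with `estimate = NA` wherever
#'   `positive` is `FALSE`, plus the `calibration_min` used. `display`
#'   renders "-" for negatives and "<1%" (etc.) for below-calibration
#'   estimates, with proportions rounded to one decimal.
#' @export
screen_samples <- function(models, unknowns, calibration_min = 1) {
  rows <- list()
  for (v in names(models)) {
    mv <- models[[v]]
    qual <- plsda_predict(mv$da, pretreat_apply(mv$da_fitted, unknowns))
    est <- rep(NA_real_, length(qual$labels))
    if (any(qual$labels)) {
      pos <- which(qual$labels)
      xq <- pretreat_apply(mv$reg_fitted, subset_samples(unknowns, pos))
      est[pos] <- pls_predict(mv$reg, xq)
    }
    below <- !is.na(est) & est < calibration_min
    display <- ifelse(
      !qual$labels, "-",
      ifelse(below, paste0("<", calibration_min, "%"),
             paste0(round(est, 1), "%"))
    )
    rows[[v]] <- data.frame(
      sample_id = unknowns$sample_ids, variety = v,
      positive = qual$labels, estimate = est,
      below_calibration = below, display = display,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(table = out, calibration_min = calibration_min),
            class = "screening_report")
}

#' Variety-by-sample display table of a screening report
#'
#' @param report a `screening_report`.
#' @return a data.frame with one row per variety and one column per sample,
#'   holding the display strings ("-" for qualitative negatives).
#' @export
screening_table <- function(report) {
  tab <- report$table
  samples <- unique(tab$sample_id)
  varieties <- unique(tab$variety)
  wide <- do.call(rbind, lapply(varieties, function(v) {
    tab$display[tab$variety == v][match(samples,
                                        tab$sample_id[tab$variety == v])]
  }))
  out <- data.frame(variety = varieties, wide, stringsAsFactors = FALSE)
  names(out) <- c("variety", samples)
  out
}

#' Absolute prediction errors against declared proportions
#'
#' @param predicted,declared numeric vectors of percent proportions.
#' @return `abs(predicted - declared)`, element-wise.
#' @export
prediction_errors <- function(predicted, declared) {
  if (length(predicted) != length(declared)) stop("length mismatch")
  abs(predicted - declared)
}

# commercial-like unknowns: uneven proportions (roughly 0.5-40% minors with
# one dominant remainder), a shape the equal-proportion calibration never saw
simulate_commercial_composition <- function(varieties, n_samples, seed) {
  nv <- length(varieties)
  with_local_seed(seed, {
    rows <- list(); ids <- character(0)
    for (i in seq_len(n_samples)) {
      k <- sample(2:4, 1L)
      members <- sort(sample.int(nv, k))
      minors <- stats::runif(k - 1L, 0.5, 40)
      if (sum(minors) > 60) minors <- minors * (60 / sum(minors))
      p <- numeric(nv)
      p[members[-1L]] <- minors
      p[members[1L]] <- 100 - sum(minors)
      rows[[i]] <- p
      ids <- c(ids, paste0("commercial_", i))
    }
  })
  composition_table(ids, varieties, do.call(rbind, rows),
                    design = data.frame(label = rep("commercial", n_samples),
                                        target = NA_character_,
                                        stringsAsFactors = FALSE))
}

#' Run the full synthetic experiment end to end
#'
#' Generates the complete design (all k-subset equal blends plus the
#' trituration series), synthesizes spectra, runs the per-variety
#' qualitative/quantitative workflows, screens a set of commercial-like
#' synthetic unknowns with uneven proportions, and assembles a manifest
#' (seed, mode, configuration) making the run byte-reproducible. When
#' `out_dir` is given, spectra/composition CSVs, per-variety selection
#' tables, the LOD table, the screening table and the manifest are written
#' there.
#'
#' @param seed integer master seed; drives the generator, the fold
#'   assignments and the unknown-sample compositions.
#' @param mode `"NIR"` or `"MIDIR"`.
#' @param n_unknowns number of commercial-like unknowns to screen
#'   (default 5).
#' @param out_dir optional output directory for CSV reports.
#' @param varieties variety names (default [default_varieties()]).
#' @param config optional [generator_config()]; defaults to
#'   `generator_config(mode = mode, seed = seed)`.
#' @param ... further arguments passed to [run_variety_workflow()]
#'   (e.g. `max_lv`, `folds`, `test_fraction`).
#' @return an object of class `experiment_bundle`: `data` (spectra +
#'   composition), `workflows` (named list of `variety_workflow`s),
#'   `screening` (a `screening_report`), `unknown_truth` (the unknowns'
#'   composition), `summary` (per-variety data.frame of chosen models,
#'   CCRs, RMSEPs and LODs) and `manifest`.
#' @export
run_full_experiment <- function(seed, mode = c("NIR", "MIDIR"),
                                n_unknowns = 5L, out_dir = NULL,
                                varieties = default_varieties(),
                                config = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(config)) config <- generator_config(mode = mode, seed = seed)
  endmembers <- generate_endmembers(config, varieties)
  design <- bind_designs(build_mixture_design(varieties),
                         build_trituration_design(varieties))
  synth <- synthesize_spectra(design, endmembers, config)
  spectra <- synth$spectra
  if (mode == "MIDIR") spectra <- cut_region(spectra, 650, 2000)

  workflows <- list()
  for (i in seq_along(varieties)) {
    workflows[[varieties[i]]] <- run_variety_workflow(
      spectra, synth$composition, varieties[i],
      seed = seed + 10L * i, ...
    )
  }

  unknown_comp <- simulate_commercial_composition(varieties, n_unknowns,
                                                  seed + 500L)
  unknown_cfg <- config
  unknown_cfg$seed <- config$seed + 501L
  unknown_spectra <- synthesize_spectra(unknown_comp, endmembers,
                                        unknown_cfg)$spectra
  if (mode == "MIDIR") unknown_spectra <- cut_region(unknown_spectra,
                                                     650, 2000)
  models <- lapply(workflows, function(w) {
    list(da = w$classification$chosen_model,
         da_fitted = w$classification$chosen_fitted,
         reg = w$regression$chosen_model,
         reg_fitted = w$regression$chosen_fitted)
  })
  screening <- screen_samples(models, unknown_spectra)

  summary_tab <- do.call(rbind, lapply(workflows, function(w) {
    data.frame(
      variety = w$variety,
      qual_pretreatment = w$classification$chosen,
      qual_n_lv = w$classification$chosen_n_lv,
      ccr_test = w$classification$test_metrics$ccr,
      ccr_cv = w$classification$cv_metrics$ccr,
      lod = w$lod$lod_label,
      quant_pretreatment = w$regression$chosen,
      quant_n_lv = w$regression$chosen_n_lv,
      rmsep = w$regression$test_metrics$rmsep,
      rmsecv = w$regression$cv_metrics$rmsecv,
      r2p = w$regression$test_metrics$r2,
      rpd = w$regression$test_metrics$rpd,
      rer = w$regression$test_metrics$rer,
      stringsAsFactors = FALSE
    )
  }))
  rownames(summary_tab) <- NULL

  manifest <- list(
    package = "blendspec",
    version = as.character(utils::packageVersion("blendspec")),
    seed = seed, mode = mode, n_unknowns = n_unknowns,
    generator = config[setdiff(names(config), "grid")]
  )

  bundle <- structure(
    list(data = synth, endmembers = endmembers, workflows = workflows,
         screening = screening, unknown_truth = unknown_comp,
         summary = summary_tab, manifest = manifest),
    class = "experiment_bundle"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_spectra_csv(spectra, file.path(out_dir, "spectra.csv"))
    write_composition_csv(synth$composition,
                          file.path(out_dir, "composition.csv"))
    data.table::fwrite(summary_tab, file.path(out_dir, "summary.csv"))
    data.table::fwrite(screening_table(screening),
                       file.path(out_dir, "screening.csv"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(out_dir, "manifest.json"))
  }
  bundle
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat("<experiment_bundle> mode =", x$manifest$mode,
      "| seed =", x$manifest$seed, "\n")
  print(x$summary, digits = 3)
  invisible(x)
}
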