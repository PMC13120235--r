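#!/usr/bin/env Rscript
# Step 3 -- per-variety qualitative and quantitative models.
#
# For each of the six varieties: a binary PLS-DA model (present/absent) and
# a PLS1 regression of the variety proportion, each swept over the six
# pre-treatments with 10-fold CV latent-variable selection and judged on a
# duplex external test set; plus a limit of detection from the variety's
# trituration series. Writes, under results/models/:
#   qualitative_models.csv   -- chosen recipe, complexity, test/CV CCR
#   qualitative_metrics.csv  -- precision/specificity/sensitivity
#   lod.csv                  -- per-variety limits of detection
#   quantitative_models.csv  -- RMSEP, R2, RPD, RER, RMSECV, R2cv
#   <variety>_{qual,quant}.json -- serialized selected models

library(blendspec)

SEED <- 1
data_dir <- file.path("results", "data")
out_dir <- file.path("results", "models")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spectra <- read_spectra_csv(file.path(data_dir, "spectra.csv"))
composition <- read_composition_csv(file.path(data_dir, "composition.csv"))
composition$design <- data.table::fread(file.path(data_dir, "design.csv"),
                                        data.table = FALSE)[, c("label",
                                                                "target")]

qual <- list(); qmet <- list(); lods <- list(); quant <- list()
for (i in seq_along(default_varieties())) {
  v <- default_varieties()[i]
  cat("modelling", v, "...\n")
  w <- run_variety_workflow(spectra, composition, v, seed = SEED + 10L * i)
  cls <- w$classification
  qual[[v]] <- data.frame(
    variety = v, n_lv = cls$chosen_n_lv, pretreatment = cls$chosen,
    ccr_test = round(cls$test_metrics$ccr, 2),
    ccr_cv = round(cls$cv_metrics$ccr, 2)
  )
  qmet[[v]] <- data.frame(
    variety = v,
    precision_test = round(cls$test_metrics$precision, 2),
    precision_cv = round(cls$cv_metrics$precision, 2),
    specificity_test = round(cls$test_metrics$specificity, 2),
    specificity_cv = round(cls$cv_metrics$specificity, 2),
    sensitivity_test = round(cls$test_metrics$sensitivity, 2),
    sensitivity_cv = round(cls$cv_metrics$sensitivity, 2)
  )
  lods[[v]] <- data.frame(
    variety = v, lod = w$lod$lod_label,
    flags = paste(ifelse(w$lod$positive_flags, "+", "-"), collapse = "")
  )
  reg <- w$regression
  quant[[v]] <- data.frame(
    variety = v, n_lv = reg$chosen_n_lv, pretreatment = reg$chosen,
    rmsep = round(reg$test_metrics$rmsep, 3),
    r2p = round(reg$test_metrics$r2, 3),
    rpd = round(reg$test_metrics$rpd, 1),
    rer = round(reg$test_metrics$rer, 1),
    rmsecv = round(reg$cv_metrics$rmsecv, 3),
    r2cv = round(reg$cv_metrics$r2cv, 3)
  )
  write_model(cls$chosen_model, file.path(out_dir, paste0(v, "_qual.json")),
              fitted = cls$chosen_fitted)
  write_model(reg$chosen_model, file.path(out_dir, paste0(v, "_quant.json")),
              fitted = reg$chosen_fitted)
}

data.table::fwrite(do.call(rbind, qual),
                   file.path(out_dir, "qualitative_models.csv"))
data.table::fwrite(do.call(rbind, qmet),
                   file.path(out_dir, "qualitative_metrics.csv"))
data.table::fwrite(do.call(rbind, lods), file.path(out_dir, "lod.csv"))
data.table::fwrite(do.call(rbind, quant),
                   file.path(out_dir, "quantitative_models.csv"))

cat("\nqualitative models:\n")
print(do.call(rbind, qual), row.names = FALSE)
cat("\nlimits of detection:\n")
print(do.call(rbind, lods), row.names = FALSE)
cat("\nquantitative models:\n")
print(do.call(rbind, quant), row.names = FALSE)
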