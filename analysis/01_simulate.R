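#!/usr/bin/env Rscript
# Step 1 -- simulate the study's sample set.
#
# Six highly similar endmember spectra (one per variety) are generated and
# blended into the complete mixture design: every nonempty k-subset of the
# six varieties in equal proportions (63 blends including the pures) plus
# the trituration series (1, 2, 5, 8% of each variety in the equal quinary
# background; 24 blends), for 87 samples in total. Observed NIR spectra add
# multiplicative scatter, an affine baseline and white noise at the default
# settings. Everything is written under results/data/.

library(blendspec)

SEED <- 1
out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

config <- generator_config(mode = "NIR", seed = SEED)
endmembers <- generate_endmembers(config)
design <- bind_designs(build_mixture_design(), build_trituration_design())
synth <- synthesize_spectra(design, endmembers, config)

write_spectra_csv(synth$spectra, file.path(out_dir, "spectra.csv"))
write_composition_csv(synth$composition,
                      file.path(out_dir, "composition.csv"))
data.table::fwrite(
  cbind(data.frame(sample_id = synth$composition$sample_ids),
        synth$composition$design),
  file.path(out_dir, "design.csv")
)
writeLines(jsonlite::toJSON(
  c(list(seed = SEED), config[setdiff(names(config), "grid")]),
  auto_unbox = TRUE, digits = NA, pretty = TRUE
), file.path(out_dir, "generator_config.json"))

cors <- cor(t(endmembers$spectra))
cat("simulated", length(synth$composition$sample_ids), "samples on",
    length(synth$spectra$grid), "NIR channels\n")
cat("endmember similarity: min pairwise r =",
    round(min(cors[upper.tri(cors)]), 4), "\n")
cat("design:", paste(names(table(design$design$label)),
                     table(design$design$label), collapse = ", "), "\n")
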