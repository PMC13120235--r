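#!/usr/bin/env Rscript
# Step 2 -- duplex train/test partitions.
#
# The duplex algorithm picks external test sets that span the spectral data
# space, always on the raw (un-pre-treated) spectra. The qualitative models
# use the 63 subset-design samples; the quantitative model for each variety
# uses its 36 positive samples (32 subset rows + 4 targeted triturations).
# Both splits take 20% for testing. The id lists are written under
# results/splits/.

library(blendspec)

data_dir <- file.path("results", "data")
out_dir <- file.path("results", "splits")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spectra <- read_spectra_csv(file.path(data_dir, "spectra.csv"))
composition <- read_composition_csv(file.path(data_dir, "composition.csv"))
design <- data.table::fread(file.path(data_dir, "design.csv"),
                            data.table = FALSE)

subset_rows <- which(design$label != "trituration")
cls <- duplex_split(subset_samples(spectra, subset_rows),
                    round(0.2 * length(subset_rows)))
ids <- spectra$sample_ids[subset_rows]
data.table::fwrite(
  data.frame(sample_id = ids,
             set = ifelse(seq_along(ids) %in% cls$test_indices,
                          "test", "train")),
  file.path(out_dir, "classification_split.csv")
)
cat("classification:", length(cls$train_indices), "train /",
    length(cls$test_indices), "test samples\n")

for (v in default_varieties()) {
  prop <- composition$proportions[, v]
  pos <- which((design$label != "trituration" & prop > 0) |
                 (design$label == "trituration" & design$target == v))
  sp <- duplex_split(subset_samples(spectra, pos), round(0.2 * length(pos)))
  ids <- spectra$sample_ids[pos]
  data.table::fwrite(
    data.frame(sample_id = ids,
               set = ifelse(seq_along(ids) %in% sp$test_indices,
                            "test", "train")),
    file.path(out_dir, paste0("regression_split_", v, ".csv"))
  )
  cat("regression ", v, ": ", length(sp$train_indices), " train / ",
      length(sp$test_indices), " test\n", sep = "")
}
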