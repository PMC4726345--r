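#!/usr/bin/env Rscript
# Quantile-normalize the profile intensities, merge each dye-swap pair into
# one per-sample profile, and run the pre-correction PCA QC, which should
# show the planted batch and biopsy-timing structure.

library(rifsignature)

study_dir <- "scratch/study"
profiles <- read_expression(file.path(study_dir, "m_values.tsv"),
                            file.path(study_dir, "intensities.tsv"),
                            file.path(study_dir, "annotation.tsv"))
pairs <- utils::read.delim(file.path(study_dir, "dye_swap_pairs.tsv"),
                           stringsAsFactors = FALSE)
sheet <- read_sample_sheet(file.path(study_dir, "sample_sheet.tsv"))

profiles$intensities <- quantile_normalize(profiles$intensities)
merged <- merge_dye_swaps(profiles, pairs)
write_expression(merged,
                 file.path(study_dir, "merged_m.tsv"),
                 file.path(study_dir, "merged_intensity.tsv"),
                 file.path(study_dir, "annotation.tsv"))

qc <- pca_qc(merged, sheet, covariates = c("class_label", "batch",
                                           "biopsy_day", "center"),
             n_components = 5)
assoc <- qc$associations
assoc$variance_explained <- qc$variance_explained[assoc$component]
write_table(assoc, "results/02_pca_before_correction.tsv")

top <- assoc[assoc$p_value < 0.05 / nrow(assoc), ]
cat("Merged", length(profiles$sample_ids), "profiles into",
    length(merged$sample_ids), "samples.\n")
cat("PCA before correction: Bonferroni-significant associations:\n")
print(top[order(top$p_value), c("component", "covariate", "p_value")],
      row.names = FALSE)
cat("Full table in results/02_pca_before_correction.tsv\n")
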