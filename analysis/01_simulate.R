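#!/usr/bin/env Rscript
# Generate the synthetic endometrial RIF study used by the whole analysis:
# 115 samples (43 RIF / 72 control) profiled as dye-swap pairs against a
# common reference, with planted class, batch, biopsy-timing and gene-set
# structure. Bulky matrices go to scratch/study/, summary tables to results/.

library(rifsignature)

seed <- 42L
out <- "scratch/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

design <- simulation_design(seed = seed)
study <- generate_dataset(design)

write_expression(study$profiles,
                 file.path(out, "m_values.tsv"),
                 file.path(out, "intensities.tsv"),
                 file.path(out, "annotation.tsv"))
write_table(study$pairs, file.path(out, "dye_swap_pairs.tsv"))
write_table(as.data.frame(study$sheet), file.path(out, "sample_sheet.tsv"))
write_gmt(study$sets, file.path(out, "gene_sets.gmt"))
write_table(data.frame(probe_id = study$truth$affected_probes,
                       gene_id = study$truth$affected_genes,
                       sign = study$truth$signs),
            file.path(out, "truth_signature.tsv"))
write_table(data.frame(sample_id = names(study$truth$subtype),
                       subtype = study$truth$subtype),
            file.path(out, "truth_subtypes.tsv"))

sheet <- study$sheet
summary_tab <- data.frame(
  quantity = c("samples", "rif", "control", "profiles", "genes",
               "planted_signature_genes", "planted_down_frac",
               "control_implantation_rate", "rif_implantation_rate"),
  value = c(nrow(sheet), sum(sheet$class_label == "RIF"),
            sum(sheet$class_label == "control"),
            length(study$profiles$sample_ids), design$n_genes,
            length(study$truth$affected_probes),
            mean(study$truth$signs == -1),
            sum(sheet$n_implantations[sheet$class_label == "control"]) /
              sum(sheet$n_transfers[sheet$class_label == "control"]),
            sum(sheet$n_implantations[sheet$class_label == "RIF"]) /
              sum(sheet$n_transfers[sheet$class_label == "RIF"])))
write_table(summary_tab, "results/01_simulation_summary.tsv")

cat("Simulated", nrow(sheet), "samples (",
    sum(sheet$class_label == "RIF"), "RIF /",
    sum(sheet$class_label == "control"), "control ) as",
    length(study$profiles$sample_ids), "dye-swap profiles over",
    design$n_genes, "probes.\n")
cat("Planted a", design$n_signature_genes, "gene signature,",
    round(100 * mean(study$truth$signs == -1)), "% down-regulated;",
    "implantation rates",
    sprintf("%.1f%% (control) vs %.1f%% (RIF).\n",
            100 * summary_tab$value[8], 100 * summary_tab$value[9]))
cat("Artifacts in", out, "; summary in results/01_simulation_summary.tsv\n")
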