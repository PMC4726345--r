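#!/usr/bin/env Rscript
# Diagnostic evaluation of the signature classifier: confusion metrics with
# Wilson 95% CIs, two-sided Fisher exact P, and ROC/AUC for the LOOCV
# (discovery) and independent validation score sets.

library(rifsignature)

loocv_scores <- utils::read.delim("results/04_scores_loocv.tsv",
                                  stringsAsFactors = FALSE)
val_scores <- utils::read.delim("results/04_scores_validation.tsv",
                                stringsAsFactors = FALSE)

evaluate <- function(scored, label) {
  rep <- classification_report(scored)
  m <- rep$metrics
  m$set <- label
  m$fisher_p <- rep$fisher_p
  m$auc <- rep$roc$auc
  m$auc_ci_low <- rep$roc$ci["low"]
  m$auc_ci_high <- rep$roc$ci["high"]
  list(metrics = m, roc = cbind(set = label, rep$roc$curve))
}

disc <- evaluate(loocv_scores, "discovery_loocv")
val <- evaluate(val_scores, "validation")

write_table(rbind(disc$metrics, val$metrics), "results/05_metrics.tsv")
write_table(rbind(disc$roc, val$roc), "results/05_roc.tsv")

show <- function(m, label) {
  cat(label, ":\n", sep = "")
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %5.1f%% (%.1f-%.1f)\n", m$metric[i],
                m$estimate[i], m$ci_low[i], m$ci_high[i]))
  }
  cat(sprintf("  Fisher P = %.3g, AUC = %.3f (%.3f-%.3f)\n",
              m$fisher_p[1], m$auc[1], m$auc_ci_low[1], m$auc_ci_high[1]))
}
show(disc$metrics, "Discovery set (LOOCV)")
show(val$metrics, "Independent validation set")
cat("Tables in results/05_metrics.tsv and results/05_roc.tsv\n")
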