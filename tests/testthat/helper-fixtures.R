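# Shared fixtures and independent oracles, all built in code.

# Small expression dataset with hand-set values.
tiny_dataset <- function(m, a = NULL, genes = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("P%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  if (is.null(a)) a <- matrix(8, nrow(m), ncol(m), dimnames = dimnames(m))
  if (is.null(genes)) genes <- paste0("G_", rownames(m))
  expression_dataset(rownames(m), genes, m, a, colnames(m))
}

# Minimal valid sample sheet for the given ids and class labels.
tiny_sheet <- function(ids, classes, batch = "c2b1", day = 7L) {
  sample_sheet(data.frame(
    sample_id = ids, class_label = classes,
    cohort = ifelse(batch == "c1", 1L, 2L), batch = batch, center = "A",
    biopsy_day = day, n_transfers = 4L, n_implantations = 0L,
    stringsAsFactors = FALSE))
}

# Reduced simulation design for fast unit tests (not the study defaults).
small_design <- function(seed, ...) {
  simulation_design(n_genes = 400L, n_signature_genes = 40L,
                    n_gene_sets = 10L, seed = seed, ...)
}

# Independent two-sided Fisher oracle: exhaustive enumeration of the
# hypergeometric support with the minimum-likelihood rule.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent AUC oracle: pairwise concordance with half credit for ties.
auc_concordance_oracle <- function(scores, truth) {
  pos <- scores[truth == "RIF"]
  neg <- scores[truth == "control"]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Run the full pipeline on a generated study; shared by several tests.
run_full_pipeline <- function(study, config, n_discovery = 81L) {
  prep <- preprocess_study(study)
  list(prep = prep,
       res = run_discovery_pipeline(prep$dataset, study$sheet, config,
                                    n_discovery = n_discovery))
}
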