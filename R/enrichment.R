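#' Collapse probe-level M values to gene level
#'
#' Averages M values across a gene's probes (default) or keeps the probe
#' with the highest mean intensity. Unannotated probes are kept under their
#' own probe id.
#'
#' @param dataset an `expression_dataset`.
#' @param method `"average"` or `"best_probe"` (highest mean intensity).
#' @return A numeric gene x sample matrix.
#' @export
collapse_to_genes <- function(dataset, method = c("average", "best_probe")) {
  method <- match.arg(method)
  gene <- dataset$gene_ids
  gene[is.na(gene)] <- dataset$probe_ids[is.na(gene)]
  if (method == "average") {
    m <- rowsum(dataset$m_values, gene)
    counts <- table(gene)
    m / as.integer(counts[rownames(m)])
  } else {
    best <- tapply(seq_along(gene), gene, function(i) {
      i[which.max(rowMeans(dataset$intensities[i, , drop = FALSE]))]
    })
    out <- dataset$m_values[unlist(best), , drop = FALSE]
    rownames(out) <- names(best)
    out
  }
}

#' Per-gene two-sample t statistics, RIF vs. control
#'
#' Pooled-variance two-sample t per gene on the (probe-collapsed) log2 fold
#' changes, oriented RIF minus control. Genes with zero pooled variance get
#' t = 0 with a warning.
#'
#' @param dataset an `expression_dataset`.
#' @param sheet a `rif_sample_sheet`; needs >= 2 samples per class.
#' @param collapse probe-to-gene collapse method, see [collapse_to_genes()].
#' @return Named numeric vector of t statistics per gene.
#' @export
gene_t_statistics <- function(dataset, sheet, collapse = "average") {
  y <- sheet$class_label[match(dataset$sample_ids, sheet$sample_id)]
  if (any(table(y) < 2) || length(unique(y)) < 2) {
    stop("need >= 2 samples per class")
  }
  m <- collapse_to_genes(dataset, collapse)
  x1 <- m[, y == "RIF", drop = FALSE]
  x0 <- m[, y == "control", drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  mu1 <- rowMeans(x1); mu0 <- rowMeans(x0)
  ss1 <- rowSums((x1 - mu1)^2)
  ss0 <- rowSums((x0 - mu0)^2)
  sp2 <- (ss1 + ss0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  if (any(se == 0)) warning(sum(se == 0), " gene(s) with zero pooled variance; t = 0")
  t <- ifelse(se == 0, 0, (mu1 - mu0) / se)
  names(t) <- rownames(m)
  t
}

#' Parametric gene-set Z-score
#'
#' `Z = (mean_set - mean_all) * sqrt(m) / sd_all`, where the mean and SD
#' (n-1 denominator) are over all gene t statistics and `m` is the number of
#' set members present. Under no enrichment and many genes, Z is
#' approximately standard normal.
#'
#' @param t_values named per-gene t statistics.
#' @param member_genes the set's member gene ids.
#' @return The Z score, or `NA` if no member is present (with a warning).
#' @export
gene_set_zscore <- function(t_values, member_genes) {
  present <- intersect(member_genes, names(t_values))
  m <- length(present)
  if (m == 0) {
    warning("no set member present in the data; set skipped")
    return(NA_real_)
  }
  (mean(t_values[present]) - mean(t_values)) * sqrt(m) / stats::sd(t_values)
}

#' Parametric gene-set enrichment table
#'
#' For every gene set: the Z-score on the per-gene t statistics, the
#' two-sided normal P `2 * pnorm(-|Z|)`, the Bonferroni-corrected P (over
#' the sets with at least one member present), and the direction (negative Z
#' means down-regulated in RIF). Rows are sorted by raw P ascending.
#' Enrichment runs on the full corrected transcriptome, not only signature
#' genes.
#'
#' @param dataset an `expression_dataset`.
#' @param sheet a `rif_sample_sheet`.
#' @param sets a `gene_set_collection`.
#' @param collapse probe-to-gene collapse method.
#' @return A data.frame: `set_id`, `description`, `set_size_used`, `z_score`,
#'   `p_raw`, `p_bonferroni`, `direction`.
#' @export
enrichment_table <- function(dataset, sheet, sets, collapse = "average") {
  if (!length(sets)) stop("empty gene-set collection")
  t <- gene_t_statistics(dataset, sheet, collapse)
  rows <- lapply(names(sets), function(id) {
    present <- intersect(sets[[id]]$genes, names(t))
    if (!length(present)) {
      warning("no set member present in the data; skipping ", id)
      return(NULL)
    }
    z <- gene_set_zscore(t, present)
    data.frame(set_id = id, description = sets[[id]]$description,
               set_size_used = length(present), z_score = z,
               p_raw = 2 * stats::pnorm(-abs(z)),
               direction = if (z >= 0) "up_in_RIF" else "down_in_RIF",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no gene set has members present in the data")
  tab$p_bonferroni <- pmin(1, tab$p_raw * nrow(tab))
  tab <- tab[order(tab$p_raw), c("set_id", "description", "set_size_used",
                                 "z_score", "p_raw", "p_bonferroni",
                                 "direction")]
  rownames(tab) <- NULL
  tab
}
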