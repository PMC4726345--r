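#' Quantile normalization of an intensity matrix
#'
#' Forces every column to the same distribution: the across-column mean of
#' sorted values. Within-column rank order is preserved; ties are resolved by
#' first occurrence so that all columns end with identical value multisets.
#'
#' @param x numeric matrix (probes x samples), no missing values, >= 2 columns.
#' @return The normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("quantile_normalize: missing values are not supported")
  if (ncol(x) < 2) stop("quantile_normalize: need at least 2 columns")
  target <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) target[rank(col, ties.method = "first")])
  dimnames(out) <- dimnames(x)
  out
}

#' Merge one dye-swap profile pair
#'
#' Two-channel hybridizations are run in pairs with the fluorophores swapped
#' between sample and common reference; the reverse profile is
#' reference-over-sample oriented. Merging averages the re-oriented fold
#' changes, `(M_fwd + (-M_rev)) / 2` per probe, cancelling dye bias;
#' intensities are averaged as-is.
#'
#' @param m_fwd,m_rev named numeric vectors of per-probe M values
#'   (forward / reverse orientation); must cover identical probes.
#' @param a_fwd,a_rev optional matched intensity vectors.
#' @return A list with `m` (merged M values) and, when intensities are given,
#'   `intensity`.
#' @export
merge_dye_swap <- function(m_fwd, m_rev, a_fwd = NULL, a_rev = NULL) {
  if (!is.null(names(m_fwd)) || !is.null(names(m_rev))) {
    d1 <- setdiff(names(m_fwd), names(m_rev))
    d2 <- setdiff(names(m_rev), names(m_fwd))
    if (length(d1) || length(d2)) {
      stop("probe sets differ; only in forward: [",
           paste(d1, collapse = ", "), "]; only in reverse: [",
           paste(d2, collapse = ", "), "]")
    }
    m_rev <- m_rev[names(m_fwd)]
  } else if (length(m_fwd) != length(m_rev)) {
    stop("probe sets differ: ", length(m_fwd), " vs ", length(m_rev),
         " probes")
  }
  out <- list(m = (m_fwd - m_rev) / 2)
  if (!is.null(a_fwd) && !is.null(a_rev)) out$intensity <- (a_fwd + a_rev) / 2
  out
}

#' Merge all dye-swap pairs of a profile-level dataset
#'
#' @param profiles an `expression_dataset` whose columns are individual
#'   dye-swap profiles.
#' @param pairs data.frame with columns `sample_id`, `fwd`, `rev` naming the
#'   forward and reverse profile of each sample.
#' @return An `expression_dataset` with one column per sample.
#' @export
merge_dye_swaps <- function(profiles, pairs) {
  miss <- setdiff(c(pairs$fwd, pairs$rev), profiles$sample_ids)
  if (length(miss)) stop("profiles missing from dataset: ",
                         paste(miss, collapse = ", "))
  m <- (profiles$m_values[, pairs$fwd, drop = FALSE] -
          profiles$m_values[, pairs$rev, drop = FALSE]) / 2
  a <- (profiles$intensities[, pairs$fwd, drop = FALSE] +
          profiles$intensities[, pairs$rev, drop = FALSE]) / 2
  expression_dataset(profiles$probe_ids, profiles$gene_ids, m, a,
                     pairs$sample_id)
}

#' Filter probes on median intensity and fold-change variability
#'
#' Removes probes whose median log2 intensity over the reference (signature
#' discovery) samples is at or below `intensity_cutoff`, and probes whose
#' fold-change standard deviation over those samples is strictly below the
#' median SD of all probes. Both criteria are computed on the full pre-filter
#' probe universe; low-intensity probes still contribute to the median SD.
#' The intensity boundary is inclusive (a probe exactly at the cutoff is
#' removed); the SD boundary keeps ties at the median.
#'
#' @param dataset an `expression_dataset`.
#' @param reference_sample_ids the samples (discovery set) on which medians
#'   and SDs are computed.
#' @param intensity_cutoff log2 intensity cutoff (default 6).
#' @return A list with `dataset` (filtered) and `decisions` (a data.frame
#'   recording, for every probe, its median intensity, SD, whether kept, and
#'   the reason: `low_intensity`, `low_sd`, or `kept`).
#' @export
filter_probes <- function(dataset, reference_sample_ids, intensity_cutoff = 6) {
  if (!length(reference_sample_ids)) stop("empty reference sample set")
  miss <- setdiff(reference_sample_ids, dataset$sample_ids)
  if (length(miss)) stop("reference samples not in dataset: ",
                         paste(miss, collapse = ", "))
  a <- dataset$intensities[, reference_sample_ids, drop = FALSE]
  m <- dataset$m_values[, reference_sample_ids, drop = FALSE]
  med_int <- apply(a, 1, stats::median)
  sds <- apply(m, 1, stats::sd)
  med_sd <- stats::median(sds)
  low_int <- med_int <= intensity_cutoff
  low_sd <- sds < med_sd
  kept <- !low_int & !low_sd
  reason <- ifelse(kept, "kept", ifelse(low_int, "low_intensity", "low_sd"))
  decisions <- data.frame(probe_id = dataset$probe_ids,
                          median_intensity = med_int,
                          fold_change_sd = sds,
                          kept = kept, reason = reason,
                          stringsAsFactors = FALSE, row.names = NULL)
  list(dataset = subset_dataset(dataset, probes = which(kept)),
       decisions = decisions)
}
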