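#' Construct an expression dataset
#'
#' Bundles a probe-by-sample matrix of log2 fold changes (M values, sample vs.
#' a common reference RNA) with the matched matrix of log2 mean spot
#' intensities and a probe-to-gene annotation. Rows align with `probe_ids`,
#' columns with `sample_ids`; both matrices must have identical shape.
#'
#' @param probe_ids character vector of unique probe identifiers.
#' @param gene_ids per-probe gene symbols; `NA` where a probe has no
#'   annotation (kept, never dropped).
#' @param m_values numeric probe x sample matrix of log2 fold changes.
#' @param intensities numeric probe x sample matrix of log2 intensities.
#' @param sample_ids character vector of unique sample (profile) identifiers.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(probe_ids, gene_ids, m_values, intensities,
                               sample_ids) {
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  m_values <- as.matrix(m_values)
  intensities <- as.matrix(intensities)
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe ids: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!identical(dim(m_values), dim(intensities))) {
    stop(sprintf(
      "shape mismatch: m_values is %d x %d but intensities is %d x %d",
      nrow(m_values), ncol(m_values), nrow(intensities), ncol(intensities)))
  }
  if (nrow(m_values) != length(probe_ids)) {
    stop(sprintf("matrix has %d rows but %d probe ids given",
                 nrow(m_values), length(probe_ids)))
  }
  if (ncol(m_values) != length(sample_ids)) {
    stop(sprintf("matrix has %d columns but %d sample ids given",
                 ncol(m_values), length(sample_ids)))
  }
  if (length(gene_ids) != length(probe_ids)) {
    stop("gene_ids must have one entry per probe (NA allowed)")
  }
  dimnames(m_values) <- list(probe_ids, sample_ids)
  dimnames(intensities) <- list(probe_ids, sample_ids)
  structure(
    list(probe_ids = probe_ids, gene_ids = as.character(gene_ids),
         m_values = m_values, intensities = intensities,
         sample_ids = sample_ids),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d probes x %d samples (%d annotated genes)\n",
              length(x$probe_ids), length(x$sample_ids),
              length(unique(x$gene_ids[!is.na(x$gene_ids)]))))
  invisible(x)
}

#' Subset an expression dataset by probes and/or samples
#'
#' @param dataset an `expression_dataset`.
#' @param probes probe ids (or logical/integer index) to keep; `NULL` keeps all.
#' @param samples sample ids (or index) to keep; `NULL` keeps all.
#' @return A new `expression_dataset`.
#' @export
subset_dataset <- function(dataset, probes = NULL, samples = NULL) {
  pi <- if (is.null(probes)) seq_along(dataset$probe_ids) else probes
  si <- if (is.null(samples)) seq_along(dataset$sample_ids) else samples
  if (is.character(pi)) {
    miss <- setdiff(pi, dataset$probe_ids)
    if (length(miss)) stop("unknown probes: ", paste(miss, collapse = ", "))
    pi <- match(pi, dataset$probe_ids)
  }
  if (is.character(si)) {
    miss <- setdiff(si, dataset$sample_ids)
    if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    si <- match(si, dataset$sample_ids)
  }
  expression_dataset(
    probe_ids = dataset$probe_ids[pi],
    gene_ids = dataset$gene_ids[pi],
    m_values = dataset$m_values[pi, si, drop = FALSE],
    intensities = dataset$intensities[pi, si, drop = FALSE],
    sample_ids = dataset$sample_ids[si])
}

#' Validate and construct a sample sheet
#'
#' Per-sample metadata: class label (RIF / control), cohort, processing batch,
#' recruiting center, biopsy day relative to the LH surge, and the pre-biopsy
#' embryo-transfer and implantation counts.
#'
#' @param df a data.frame with columns `sample_id`, `class_label`
#'   (`"RIF"`/`"control"`), `cohort` (1/2), `batch` (`"c1"`, `"c2b1"`,
#'   `"c2b2"`), `center` (`"A"`/`"B"`), `biopsy_day` (integer in 5..8),
#'   `n_transfers`, `n_implantations`; optional `split` (`"discovery"`,
#'   `"validation"`, `"unassigned"`).
#' @return The validated data.frame with class `rif_sample_sheet`.
#' @export
sample_sheet <- function(df) {
  req <- c("sample_id", "class_label", "cohort", "batch", "center",
           "biopsy_day", "n_transfers", "n_implantations")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sheet")
  if (!all(df$class_label %in% c("RIF", "control"))) {
    stop("class_label must be 'RIF' or 'control'")
  }
  if (!all(df$batch %in% c("c1", "c2b1", "c2b2"))) {
    stop("batch must be one of c1, c2b1, c2b2")
  }
  if (!all(df$biopsy_day %in% 5:8)) stop("biopsy_day must be in 5..8")
  if (any(df$n_transfers < 0) || any(df$n_implantations < 0)) {
    stop("transfer/implantation counts must be nonnegative")
  }
  if (any(df$n_implantations > df$n_transfers)) {
    stop("n_implantations exceeds n_transfers for: ",
         paste(df$sample_id[df$n_implantations > df$n_transfers],
               collapse = ", "))
  }
  if (is.null(df$split)) df$split <- "unassigned"
  if (!all(df$split %in% c("discovery", "validation", "unassigned"))) {
    stop("split must be discovery/validation/unassigned")
  }
  class(df) <- c("rif_sample_sheet", "data.frame")
  df
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of the whole analysis with the study's
#' default values: 100 resampling rounds over 4/5 training subsets, top-100
#' probe lists, an inclusive selection-frequency threshold of 5, a signature
#' score cutoff of 0.5 (scores at or above call RIF), an intensity filter at
#' log2 intensity 6 (inclusive), stratification thresholds 0.1/0.9 over 1000
#' resampling rounds, and one global RNG seed from which each stage derives
#' its own child seed.
#'
#' @param n_rounds resampling rounds for signature discovery.
#' @param train_fraction fraction of discovery samples in each training fold.
#' @param n_top_genes probes retained per round by absolute signal-to-noise.
#' @param min_frequency inclusive selection-count threshold for the signature.
#' @param score_threshold probability cutoff; score >= threshold calls RIF.
#' @param intensity_cutoff log2 intensity at or below which probes are removed.
#' @param strat_thresholds error-rate cuts defining low/medium/high groups.
#' @param strat_rounds resampling rounds for patient stratification.
#' @param svm_cost soft-margin cost of the linear SVM.
#' @param rng_seed integer global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_rounds = 100L, train_fraction = 4 / 5,
                            n_top_genes = 100L, min_frequency = 5L,
                            score_threshold = 0.5, intensity_cutoff = 6,
                            strat_thresholds = c(0.1, 0.9),
                            strat_rounds = 1000L, svm_cost = 1,
                            rng_seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            length(strat_thresholds) == 2,
            strat_thresholds[1] >= 0, strat_thresholds[2] <= 1,
            strat_thresholds[1] < strat_thresholds[2],
            n_rounds >= 1, n_top_genes >= 1, min_frequency >= 1,
            strat_rounds >= 1, svm_cost > 0)
  structure(
    list(n_rounds = as.integer(n_rounds), train_fraction = train_fraction,
         n_top_genes = as.integer(n_top_genes),
         min_frequency = as.integer(min_frequency),
         score_threshold = score_threshold,
         intensity_cutoff = intensity_cutoff,
         strat_thresholds = strat_thresholds,
         strat_rounds = as.integer(strat_rounds),
         svm_cost = svm_cost, rng_seed = as.integer(rng_seed)),
    class = "pipeline_config")
}

#' Derive a deterministic child seed for a pipeline stage
#'
#' Stages (simulation, splitting, resampling, stratification) draw their
#' randomness from seeds derived from the one global seed, so each stage is
#' independently reproducible.
#'
#' @param seed integer parent seed.
#' @param stage character stage label.
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(seed, stage) {
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Detect the field separator of a delimited text file (tab canonical,
# comma accepted).
detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

read_matrix_file <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          row.names = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read an expression dataset from delimited text files
#'
#' Each matrix file carries probe ids in the first column and sample ids in
#' the header. Columns of the intensity file are aligned to the fold-change
#' file by sample id; rows are aligned by probe id through the annotation.
#'
#' @param matrix_path path to the log2 fold-change (M value) matrix.
#' @param intensity_path path to the log2 intensity matrix.
#' @param annotation_path path to a two-column (probe_id, gene_id) table;
#'   empty gene_id marks an unannotated probe.
#' @return An `expression_dataset`.
#' @export
read_expression <- function(matrix_path, intensity_path, annotation_path) {
  m <- read_matrix_file(matrix_path)
  a <- read_matrix_file(intensity_path)
  missing_samples <- setdiff(colnames(m), colnames(a))
  extra_samples <- setdiff(colnames(a), colnames(m))
  if (length(missing_samples) || length(extra_samples)) {
    stop("sample mismatch between matrix and intensity files; missing from ",
         "intensity: [", paste(missing_samples, collapse = ", "),
         "]; extra in intensity: [", paste(extra_samples, collapse = ", "), "]")
  }
  if (nrow(m) != nrow(a) || !setequal(rownames(m), rownames(a))) {
    stop(sprintf("probe mismatch: matrix has %d probes, intensity has %d (%d shared)",
                 nrow(m), nrow(a), length(intersect(rownames(m), rownames(a)))))
  }
  a <- a[rownames(m), colnames(m), drop = FALSE]
  ann <- utils::read.table(annotation_path, header = TRUE,
                           sep = detect_sep(annotation_path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  gene <- as.character(ann[[2]])[match(rownames(m), as.character(ann[[1]]))]
  expression_dataset(rownames(m), gene, m, a, colnames(m))
}

#' Read a sample sheet from a delimited text file
#'
#' @param path TSV (or CSV) file with the columns of [sample_sheet()].
#' @return A validated `rif_sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  sample_sheet(df)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, `set_id TAB description TAB
#' member...`. Duplicate members within a set are dropped.
#'
#' @param path GMT file.
#' @return A list of class `gene_set_collection`: named list of
#'   `list(description, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list()))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT line %d has %d fields (need >= 3)", i, length(f)))
    }
    sets[[f[1]]] <- list(description = f[2], genes = unique(f[-(1:2)]))
  }
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#'
#' @param sets named list; each element `list(description, genes)` with a
#'   non-empty character vector of member gene ids.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      stop("set ids must be unique and named")
    }
    for (s in sets) {
      if (!length(s$genes)) stop("gene sets must be non-empty")
    }
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$description, sets[[id]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Write a data frame as a diff-clean TSV report
#'
#' Deterministic column order (as given) and fixed numeric precision so that
#' re-runs with the same seed produce byte-identical files.
#'
#' @param table a data.frame.
#' @param path output path.
#' @param digits significant digits for numeric columns.
#' @export
write_table <- function(table, path, digits = 6) {
  out <- as.data.frame(table)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Write an expression dataset to delimited text files
#'
#' Inverse of [read_expression()]: writes the M-value matrix, the intensity
#' matrix, and the probe annotation as TSV.
#'
#' @param dataset an `expression_dataset`.
#' @param matrix_path,intensity_path,annotation_path output paths.
#' @export
write_expression <- function(dataset, matrix_path, intensity_path,
                             annotation_path) {
  wm <- function(m, p) {
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wm(dataset$m_values, matrix_path)
  wm(dataset$intensities, intensity_path)
  utils::write.table(
    data.frame(probe_id = dataset$probe_ids, gene_id = dataset$gene_ids),
    annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
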