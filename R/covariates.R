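#' Estimate a per-probe covariate effect by linear models
#'
#' Fits, for every probe, an ordinary least-squares model of the M values on
#' indicator variables for the covariate's levels (intercept plus one
#' indicator per non-reference level), using only the designated estimation
#' samples. With a single covariate in the design, each coefficient is the
#' level-vs-reference group-mean contrast. Following the study's
#' confounding-avoidance strategy, the biopsy-timing effect is estimated on
#' the cohort-2-batch-1 controls only (one batch, one class) and the batch
#' effect on all controls; the estimation subset is always an explicit
#' argument.
#'
#' @param dataset an `expression_dataset`.
#' @param sheet a `rif_sample_sheet`.
#' @param covariate `"biopsy_day"` or `"batch"` (any sheet column with >= 2
#'   levels works).
#' @param estimation_subset sample ids to fit on.
#' @param reference_level the level mapped to coefficient 0 (day 7 for
#'   timing, `"c2b1"` for batch).
#' @return A list of class `effect_model`: `covariate`, `reference_level`,
#'   `estimation_sample_ids`, `coefficients` (probe x non-reference-level
#'   matrix, log2 units), `stderr` (matched OLS standard errors).
#' @export
estimate_effect <- function(dataset, sheet, covariate, estimation_subset,
                            reference_level = if (covariate == "biopsy_day") "7" else "c2b1") {
  if (!length(estimation_subset)) stop("empty estimation subset")
  if (!covariate %in% names(sheet)) stop("unknown covariate: ", covariate)
  sub <- sheet[match(estimation_subset, sheet$sample_id), , drop = FALSE]
  if (anyNA(sub$sample_id)) stop("estimation samples missing from sheet")
  lev <- as.character(sub[[covariate]])
  tab <- table(lev)
  if (length(tab) < 2) stop("covariate '", covariate,
                            "' is constant in the estimation subset")
  if (any(tab < 2)) {
    stop("cannot estimate level(s) with <2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  if (!reference_level %in% names(tab)) {
    stop("reference level '", reference_level, "' absent from subset")
  }
  f <- stats::relevel(factor(lev), ref = reference_level)
  design <- stats::model.matrix(~f)
  colnames(design) <- c("(Intercept)", levels(f)[-1])
  fit <- limma::lmFit(dataset$m_values[, estimation_subset, drop = FALSE],
                      design)
  keep <- levels(f)[-1]
  coefs <- fit$coefficients[, keep, drop = FALSE]
  se <- fit$stdev.unscaled[, keep, drop = FALSE] * fit$sigma
  structure(list(covariate = covariate, reference_level = reference_level,
                 estimation_sample_ids = estimation_subset,
                 coefficients = coefs, stderr = se),
            class = "effect_model")
}

#' Remove an estimated covariate effect from a dataset
#'
#' Subtracts, for every sample, its covariate level's per-probe coefficient,
#' transforming the data to the model's reference level. Reference-level
#' samples are unchanged; the transformation is exactly invertible by adding
#' the coefficients back.
#'
#' @param dataset an `expression_dataset`.
#' @param model an `effect_model` from [estimate_effect()].
#' @param sheet a `rif_sample_sheet` covering every dataset sample.
#' @return The corrected `expression_dataset`.
#' @export
apply_correction <- function(dataset, model, sheet) {
  lev <- as.character(sheet[[model$covariate]][match(dataset$sample_ids,
                                                     sheet$sample_id)])
  if (anyNA(lev)) stop("samples missing from sheet")
  known <- c(model$reference_level, colnames(model$coefficients))
  bad <- setdiff(unique(lev), known)
  if (length(bad)) {
    stop("covariate level(s) absent from model: ", paste(bad, collapse = ", "))
  }
  m <- dataset$m_values
  for (l in colnames(model$coefficients)) {
    idx <- which(lev == l)
    if (length(idx)) m[, idx] <- m[, idx] - model$coefficients[, l]
  }
  out <- dataset
  out$m_values <- m
  out
}

#' Principal-component QC with covariate association
#'
#' Runs sample-space PCA on the centered M values and reports, per component,
#' the variance explained and the association with each covariate: Spearman
#' rank correlation for ordered covariates (biopsy day), a one-way ANOVA
#' variance-ratio F statistic for categorical ones (class, batch, center).
#'
#' @param dataset an `expression_dataset` with >= 3 samples.
#' @param sheet a `rif_sample_sheet`.
#' @param covariates sheet columns to test.
#' @param n_components number of leading components to report.
#' @return A list with `variance_explained` (per component, non-increasing,
#'   sums to <= 1) and `associations` (data.frame: component, covariate,
#'   statistic, p_value, test).
#' @export
pca_qc <- function(dataset, sheet,
                   covariates = c("class_label", "batch", "biopsy_day",
                                  "center"),
                   n_components = 5L) {
  if (length(dataset$sample_ids) < 3) stop("need at least 3 samples for PCA")
  x <- t(dataset$m_values)
  if (all(apply(x, 2, stats::sd) == 0)) stop("constant matrix")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  idx <- match(dataset$sample_ids, sheet$sample_id)
  rows <- list()
  for (i in seq_len(k)) {
    for (cv in covariates) {
      v <- sheet[[cv]][idx]
      if (length(unique(v)) < 2) next
      if (is.numeric(v)) {
        ct <- suppressWarnings(
          stats::cor.test(pc$x[, i], v, method = "spearman"))
        rows[[length(rows) + 1]] <- data.frame(
          component = i, covariate = cv, statistic = unname(ct$estimate),
          p_value = ct$p.value, test = "spearman",
          stringsAsFactors = FALSE)
      } else {
        an <- stats::anova(stats::lm(pc$x[, i] ~ factor(v)))
        rows[[length(rows) + 1]] <- data.frame(
          component = i, covariate = cv, statistic = an$`F value`[1],
          p_value = an$`Pr(>F)`[1], test = "anova_F",
          stringsAsFactors = FALSE)
      }
    }
  }
  list(variance_explained = ve[seq_len(k)],
       associations = do.call(rbind, rows))
}
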