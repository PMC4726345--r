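#' Stratified random split into discovery and validation sets
#'
#' Assigns samples at random to a signature discovery set and an independent
#' validation set, keeping the RIF/control ratio in each part within one
#' sample of the overall ratio (per-class sizes are the rounded class share
#' of the requested discovery size).
#'
#' @param sheet a `rif_sample_sheet`.
#' @param n_discovery discovery-set size (default 81, as in a 115-sample
#'   study split 81/34).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return A list of class `split_assignment`: `discovery_ids`,
#'   `validation_ids`, `seed`.
#' @export
split_samples <- function(sheet, n_discovery = 81L, seed = 1L) {
  classes <- split(sheet$sample_id, sheet$class_label)
  if (length(classes) < 2 || any(lengths(classes) < 2)) {
    stop("need at least 2 samples in each class")
  }
  n <- nrow(sheet)
  if (n_discovery <= 0 || n_discovery >= n) {
    stop("infeasible discovery size ", n_discovery, " for ", n, " samples")
  }
  set.seed(seed)
  disc <- character(0)
  for (cl in names(classes)) {
    k <- round(length(classes[[cl]]) * n_discovery / n)
    k <- max(1L, min(k, length(classes[[cl]]) - 1L))
    disc <- c(disc, sample(classes[[cl]], k))
  }
  disc <- sheet$sample_id[sheet$sample_id %in% disc]  # restore sheet order
  structure(list(discovery_ids = disc,
                 validation_ids = setdiff(sheet$sample_id, disc),
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' Signal-to-noise ratio of one probe
#'
#' The Golub class-separation metric `(mean_RIF - mean_control) /
#' (sd_RIF + sd_control)` with sample (n-1) standard deviations. The sign
#' carries direction; ranking uses the absolute value. Degenerate probes with
#' both SDs zero score 0 with a warning.
#'
#' @param values_rif,values_control numeric vectors, >= 2 values each.
#' @return The signed signal-to-noise score.
#' @export
signal_to_noise <- function(values_rif, values_control) {
  if (length(values_rif) < 2 || length(values_control) < 2) {
    stop("need >= 2 samples per class")
  }
  s <- stats::sd(values_rif) + stats::sd(values_control)
  if (s == 0) {
    warning("degenerate probe: both class SDs are zero; score set to 0")
    return(0)
  }
  (mean(values_rif) - mean(values_control)) / s
}

# Vectorized signal-to-noise over all probes of a matrix.
snr_matrix <- function(m, is_rif) {
  x1 <- m[, is_rif, drop = FALSE]
  x0 <- m[, !is_rif, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  mu1 <- rowMeans(x1); mu0 <- rowMeans(x0)
  sd1 <- sqrt(rowSums((x1 - mu1)^2) / (n1 - 1))
  sd0 <- sqrt(rowSums((x0 - mu0)^2) / (n0 - 1))
  denom <- sd1 + sd0
  out <- ifelse(denom == 0, 0, (mu1 - mu0) / denom)
  names(out) <- rownames(m)
  out
}

# Rank probes by |SNR|, ties broken by probe id for determinism.
rank_probes <- function(m, is_rif, n_top) {
  s <- snr_matrix(m, is_rif)
  ord <- order(-abs(s), names(s))
  names(s)[ord][seq_len(min(n_top, length(s)))]
}

#' Train a probability-calibrated linear SVM on a probe subset
#'
#' Fits a linear two-class maximum-margin classifier (e1071/libsvm) on the
#' given probes, features standardized per probe with training statistics
#' stored in the model, followed by Platt-style probability calibration: a
#' logistic regression of the class on the SVM decision value, fitted on the
#' training samples only. The calibrated score is the probability of RIF;
#' constant features are dropped with a warning.
#'
#' @param dataset an `expression_dataset` (training samples only).
#' @param sheet a `rif_sample_sheet`.
#' @param probes probe ids to use as features.
#' @param cost soft-margin cost.
#' @return A list of class `trained_classifier`.
#' @export
train_classifier <- function(dataset, sheet, probes, cost = 1) {
  miss <- setdiff(probes, dataset$probe_ids)
  if (length(miss)) stop("probes absent from dataset: ",
                         paste(miss, collapse = ", "))
  y <- sheet$class_label[match(dataset$sample_ids, sheet$sample_id)]
  if (length(unique(y)) < 2 || any(table(y) < 2)) {
    stop("need >= 2 training samples per class")
  }
  x <- t(dataset$m_values[probes, , drop = FALSE])
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(probes[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
    mu <- mu[keep]; sdv <- sdv[keep]
  }
  if (!ncol(x)) stop("no usable features left")
  xs <- scale(x, center = mu, scale = sdv)
  yf <- factor(y, levels = c("control", "RIF"))
  fit <- e1071::svm(xs, yf, kernel = "linear", cost = cost, scale = FALSE)
  dvm <- attr(stats::predict(fit, xs, decision.values = TRUE),
              "decision.values")
  # libsvm's positive decision value favors the first-named class; orient so
  # that larger always means RIF before calibrating.
  orient <- if (startsWith(colnames(dvm)[1], "RIF/")) 1 else -1
  dv <- orient * dvm[, 1]
  calib <- suppressWarnings(
    stats::glm((yf == "RIF") ~ dv, family = stats::binomial()))
  structure(list(probes = probes[keep], center = mu, scale = sdv,
                 svm = fit, orient = orient,
                 calibration = stats::coef(calib)),
            class = "trained_classifier")
}

#' Score samples with a trained classifier
#'
#' Returns the calibrated signature score (probability of RIF, in [0, 1])
#' and the class call at the threshold; a score at or above the threshold
#' calls RIF, below calls control.
#'
#' @param model a `trained_classifier`.
#' @param dataset an `expression_dataset` containing the model's probes.
#' @param sample_ids samples to score (default all).
#' @param threshold score cutoff (default 0.5).
#' @return A data.frame: `sample_id`, `score`, `call`.
#' @export
score_samples <- function(model, dataset, sample_ids = dataset$sample_ids,
                          threshold = 0.5) {
  miss <- setdiff(model$probes, dataset$probe_ids)
  if (length(miss)) stop("missing probe values: ",
                         paste(miss, collapse = ", "))
  x <- t(dataset$m_values[model$probes, sample_ids, drop = FALSE])
  if (anyNA(x)) stop("missing probe values in scoring data")
  xs <- scale(x, center = model$center, scale = model$scale)
  dv <- model$orient * attr(stats::predict(model$svm, xs,
                                           decision.values = TRUE),
                            "decision.values")[, 1]
  eta <- model$calibration[1] + model$calibration[2] * dv
  score <- 1 / (1 + exp(-eta))
  data.frame(sample_id = sample_ids, score = unname(score),
             call = ifelse(score >= threshold, "RIF", "control"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the resampling signature-discovery loop
#'
#' For `config$n_rounds` rounds: draw a training subset (`train_fraction` of
#' the discovery samples, without replacement, not class-stratified), rank
#' all probes by absolute signal-to-noise on the training subset, keep the
#' top `n_top_genes`, train the probability-calibrated linear SVM on them,
#' and score the held-out samples. Training folds missing a class (or with a
#' single sample of one) are redrawn and logged; 50 consecutive failures
#' abort. All randomness derives from `seed`.
#'
#' @param dataset filtered `expression_dataset` restricted to the discovery
#'   samples (or the full set for stratification reruns).
#' @param sheet a `rif_sample_sheet`.
#' @param config a [pipeline_config()].
#' @param seed integer seed.
#' @return A list of class `resample_rounds`; each round holds `round_index`,
#'   `train_ids`, `test_ids`, `ranked_probe_ids`, `test_scores` (data.frame
#'   with truth attached).
#' @export
run_resampling <- function(dataset, sheet, config, seed) {
  ids <- dataset$sample_ids
  y <- sheet$class_label[match(ids, sheet$sample_id)]
  n_train <- round(config$train_fraction * length(ids))
  set.seed(seed)
  rounds <- vector("list", config$n_rounds)
  for (r in seq_len(config$n_rounds)) {
    fails <- 0
    repeat {
      tr <- sample(ids, n_train)
      ytr <- y[match(tr, ids)]
      if (length(unique(ytr)) == 2 && all(table(ytr) >= 2)) break
      fails <- fails + 1
      message("round ", r, ": training fold missing a class, redrawing")
      if (fails >= 50) stop("50 consecutive degenerate training folds")
    }
    te <- setdiff(ids, tr)
    is_rif_tr <- y[match(tr, ids)] == "RIF"
    ranked <- rank_probes(dataset$m_values[, tr, drop = FALSE], is_rif_tr,
                          config$n_top_genes)
    model <- train_classifier(subset_dataset(dataset, samples = tr), sheet,
                              ranked, cost = config$svm_cost)
    sc <- score_samples(model, dataset, te,
                        threshold = config$score_threshold)
    sc$truth <- y[match(te, ids)]
    rounds[[r]] <- list(round_index = r, train_ids = tr, test_ids = te,
                        ranked_probe_ids = ranked, test_scores = sc)
  }
  structure(rounds, class = "resample_rounds")
}

#' Aggregate resampling rounds into a gene signature
#'
#' Counts how often each probe appeared in a round's top list and selects
#' probes whose count reaches `min_frequency` (inclusive). Unique genes are
#' derived through the probe-to-gene map; unannotated probes count as their
#' own gene.
#'
#' @param rounds a `resample_rounds` list.
#' @param min_frequency inclusive selection-count threshold (default 5 of
#'   100 rounds, i.e. 5%).
#' @param gene_map named character vector probe id -> gene id (NA allowed).
#' @return A list of class `signature_result`: `counts` (named, all probes
#'   ever ranked), `selected_probes`, `selected_genes`.
#' @export
aggregate_signature <- function(rounds, min_frequency = 5L, gene_map = NULL) {
  if (!length(rounds)) stop("need at least one round")
  tab <- table(unlist(lapply(rounds, `[[`, "ranked_probe_ids")))
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts <- counts[order(names(counts))]
  selected <- names(counts)[counts >= min_frequency]
  genes <- character(0)
  if (length(selected)) {
    if (is.null(gene_map)) {
      genes <- selected
    } else {
      g <- gene_map[selected]
      g[is.na(g)] <- selected[is.na(g)]  # unannotated probes are their own gene
      genes <- unique(unname(g))
    }
  } else {
    warning("empty signature: no probe reached the frequency threshold")
  }
  structure(list(counts = counts, selected_probes = selected,
                 selected_genes = genes, min_frequency = min_frequency),
            class = "signature_result")
}

#' Leave-one-out cross-validation on a fixed probe set
#'
#' Each sample is scored by a classifier trained on all other samples, using
#' the same fixed signature probes throughout (no re-selection inside the
#' loop).
#'
#' @param dataset an `expression_dataset` (discovery samples).
#' @param sheet a `rif_sample_sheet`.
#' @param probes signature probe ids.
#' @param cost SVM cost.
#' @param threshold score cutoff.
#' @return A data.frame: `sample_id`, `score`, `call`, `truth`.
#' @export
loocv <- function(dataset, sheet, probes, cost = 1, threshold = 0.5) {
  ids <- dataset$sample_ids
  y <- sheet$class_label[match(ids, sheet$sample_id)]
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    model <- train_classifier(subset_dataset(dataset, samples = ids[-i]),
                              sheet, probes, cost = cost)
    out[[i]] <- score_samples(model, dataset, ids[i], threshold = threshold)
  }
  res <- do.call(rbind, out)
  res$truth <- y
  res
}

#' Independent validation of a signature
#'
#' Trains one classifier on all discovery samples and scores the validation
#' samples. A leakage guard refuses to score any sample listed in the
#' discovery set.
#'
#' @param dataset an `expression_dataset` covering discovery and validation
#'   samples (filtered with discovery-only statistics).
#' @param sheet a `rif_sample_sheet`.
#' @param split a `split_assignment`.
#' @param probes signature probe ids.
#' @param cost SVM cost.
#' @param threshold score cutoff.
#' @return A data.frame: `sample_id`, `score`, `call`, `truth`.
#' @export
validate_signature <- function(dataset, sheet, split, probes, cost = 1,
                               threshold = 0.5) {
  leak <- intersect(split$validation_ids, split$discovery_ids)
  if (length(leak)) stop("leakage: sample(s) in both discovery and validation: ",
                         paste(leak, collapse = ", "))
  model <- train_classifier(
    subset_dataset(dataset, samples = split$discovery_ids), sheet, probes,
    cost = cost)
  res <- score_samples(model, dataset, split$validation_ids,
                       threshold = threshold)
  res$truth <- sheet$class_label[match(res$sample_id, sheet$sample_id)]
  res
}
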