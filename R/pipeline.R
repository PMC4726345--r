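#' Preprocess a generated (or read) dye-swap study
#'
#' Quantile-normalizes the profile intensities, merges each dye-swap pair,
#' then removes the biopsy-timing effect (estimated on the cohort-2-batch-1
#' controls, day 7 reference) and the batch effect (estimated on all
#' controls, cohort-2-batch-1 reference), in that order. The minor center
#' effect is deliberately left in place. Provenance of the correction order
#' and estimation subsets is attached.
#'
#' @param study a list with `profiles`, `pairs`, `sheet` (as returned by
#'   [generate_dataset()]).
#' @param correct_day,correct_batch logical switches for the two corrections.
#' @return A list: `dataset` (corrected per-sample `expression_dataset`),
#'   `day_model`, `batch_model`, `provenance`.
#' @export
preprocess_study <- function(study, correct_day = TRUE, correct_batch = TRUE) {
  profiles <- study$profiles
  profiles$intensities <- quantile_normalize(profiles$intensities)
  dataset <- merge_dye_swaps(profiles, study$pairs)
  sheet <- study$sheet
  day_model <- NULL
  batch_model <- NULL
  if (correct_day) {
    timing_ids <- sheet$sample_id[sheet$batch == "c2b1" &
                                    sheet$class_label == "control"]
    day_model <- estimate_effect(dataset, sheet, "biopsy_day", timing_ids,
                                 reference_level = "7")
    dataset <- apply_correction(dataset, day_model, sheet)
  }
  if (correct_batch) {
    control_ids <- sheet$sample_id[sheet$class_label == "control"]
    batch_model <- estimate_effect(dataset, sheet, "batch", control_ids,
                                   reference_level = "c2b1")
    dataset <- apply_correction(dataset, batch_model, sheet)
  }
  list(dataset = dataset, day_model = day_model, batch_model = batch_model,
       provenance = list(correction_order = c(if (correct_day) "biopsy_day",
                                              if (correct_batch) "batch")))
}

#' Run the full signature discovery pipeline
#'
#' Splits the samples into discovery and validation sets, filters probes on
#' discovery-set statistics only, runs the resampling signature-discovery
#' loop on the discovery samples, aggregates the signature, and evaluates it
#' by leave-one-out cross-validation (optional) and on the held-out
#' validation set.
#'
#' @param dataset corrected per-sample `expression_dataset`.
#' @param sheet a `rif_sample_sheet`.
#' @param config a [pipeline_config()]; stage seeds derive from
#'   `config$rng_seed`.
#' @param n_discovery discovery-set size.
#' @param run_loocv whether to run leave-one-out cross-validation (the
#'   slowest step).
#' @return A list: `split`, `filter`, `rounds`, `signature`, `loocv_scores`
#'   (or NULL), `validation_scores`.
#' @export
run_discovery_pipeline <- function(dataset, sheet, config = pipeline_config(),
                                   n_discovery = 81L, run_loocv = FALSE) {
  split <- split_samples(sheet, n_discovery,
                         seed = child_seed(config$rng_seed, "split"))
  sheet$split <- ifelse(sheet$sample_id %in% split$discovery_ids,
                        "discovery", "validation")
  filt <- filter_probes(dataset, split$discovery_ids,
                        config$intensity_cutoff)
  disc <- subset_dataset(filt$dataset, samples = split$discovery_ids)
  rounds <- run_resampling(disc, sheet, config,
                           seed = child_seed(config$rng_seed, "resampling"))
  gene_map <- stats::setNames(filt$dataset$gene_ids, filt$dataset$probe_ids)
  signature <- aggregate_signature(rounds, config$min_frequency, gene_map)
  loocv_scores <- NULL
  if (run_loocv && length(signature$selected_probes)) {
    loocv_scores <- loocv(disc, sheet, signature$selected_probes,
                          cost = config$svm_cost,
                          threshold = config$score_threshold)
  }
  validation_scores <- NULL
  if (length(signature$selected_probes)) {
    validation_scores <- validate_signature(filt$dataset, sheet, split,
                                            signature$selected_probes,
                                            cost = config$svm_cost,
                                            threshold = config$score_threshold)
  }
  list(split = split, filter = filt, rounds = rounds, signature = signature,
       loocv_scores = loocv_scores, validation_scores = validation_scores)
}

#' Pooled held-out scores from resampling rounds
#'
#' Collects every held-out (test-fold) score across rounds into one
#' data.frame, the input for round-level ROC summaries.
#'
#' @param rounds a `resample_rounds` list.
#' @return A data.frame: `round_index`, `sample_id`, `score`, `call`, `truth`.
#' @export
pooled_test_scores <- function(rounds) {
  do.call(rbind, lapply(rounds, function(r) {
    cbind(round_index = r$round_index, r$test_scores)
  }))
}
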