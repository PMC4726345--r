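#' Per-sample classification error rates over resampling rounds
#'
#' Reruns the per-round discovery procedure (random 4/5 training subset,
#' signal-to-noise top-list, calibrated linear SVM, held-out prediction) on
#' the full sample set for `config$strat_rounds` rounds, and tallies for each
#' sample how often it was predicted and how often that prediction was wrong.
#' With `strat_rounds` rounds each sample is expected in the test fold about
#' `strat_rounds / 5` times.
#'
#' @param dataset filtered `expression_dataset` over all samples.
#' @param sheet a `rif_sample_sheet`.
#' @param config a [pipeline_config()]; `strat_rounds` and the discovery
#'   parameters are used.
#' @param seed integer seed.
#' @return A data.frame (`error_rate_records`): `sample_id`, `class_label`,
#'   `n_predictions`, `n_errors`, `error_rate` (NA, flagged, for a sample
#'   never held out).
#' @export
error_rates <- function(dataset, sheet, config, seed) {
  strat_config <- config
  strat_config$n_rounds <- config$strat_rounds
  rounds <- run_resampling(dataset, sheet, strat_config, seed)
  ids <- dataset$sample_ids
  n_pred <- stats::setNames(integer(length(ids)), ids)
  n_err <- n_pred
  for (r in rounds) {
    sc <- r$test_scores
    n_pred[sc$sample_id] <- n_pred[sc$sample_id] + 1L
    wrong <- sc$sample_id[sc$call != sc$truth]
    n_err[wrong] <- n_err[wrong] + 1L
  }
  never <- names(n_pred)[n_pred == 0]
  if (length(never)) {
    warning("sample(s) never held out; error rate undefined: ",
            paste(never, collapse = ", "))
  }
  data.frame(sample_id = ids,
             class_label = sheet$class_label[match(ids, sheet$sample_id)],
             n_predictions = unname(n_pred), n_errors = unname(n_err),
             error_rate = ifelse(n_pred == 0, NA_real_, n_err / n_pred),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign error-rate groups
#'
#' Three groups from two thresholds: `low` below the first, `high` strictly
#' above the second, `medium` in between with both boundaries inclusive
#' (a rate of exactly 0.1 or 0.9 is medium).
#'
#' @param records output of [error_rates()] (only RIF patients are grouped
#'   in the study; pass the subset you want grouped).
#' @param thresholds ordered pair, default `c(0.1, 0.9)`.
#' @return The records with a `group` column (`low`/`medium`/`high`; NA for
#'   undefined rates).
#' @export
assign_groups <- function(records, thresholds = c(0.1, 0.9)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  r <- records$error_rate
  records$group <- ifelse(is.na(r), NA_character_,
                          ifelse(r < thresholds[1], "low",
                                 ifelse(r > thresholds[2], "high", "medium")))
  records
}

#' Compare pooled implantation outcomes between error-rate groups
#'
#' For each pair of groups, pools every pre-biopsy embryo transfer of the
#' group's members as an independent trial (implantation yes/no) and tests
#' the 2x2 table of pooled outcomes with the two-sided Fisher exact test.
#' The independence assumption ignores within-patient correlation of
#' repeated transfers; interpret the P values accordingly.
#'
#' @param records grouped records from [assign_groups()].
#' @param sheet a `rif_sample_sheet` carrying `n_transfers` and
#'   `n_implantations`.
#' @return A data.frame: `group_a`, `group_b`, per-group transfers,
#'   implantations and rates, `p_value`.
#' @export
compare_implantation <- function(records, sheet) {
  idx <- match(records$sample_id, sheet$sample_id)
  pooled <- stats::aggregate(
    cbind(transfers = sheet$n_transfers[idx],
          implantations = sheet$n_implantations[idx]),
    by = list(group = records$group), FUN = sum)
  groups <- pooled$group
  rows <- list()
  if (length(groups) < 2) {
    warning("fewer than two non-empty groups; nothing to compare")
  }
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i) next
      a <- pooled[i, ]; b <- pooled[j, ]
      if (a$transfers == 0 || b$transfers == 0) {
        warning("group without transfers skipped: ",
                if (a$transfers == 0) a$group else b$group)
        next
      }
      tab <- matrix(c(a$implantations, a$transfers - a$implantations,
                      b$implantations, b$transfers - b$implantations),
                    2, 2)
      rows[[length(rows) + 1]] <- data.frame(
        group_a = a$group, group_b = b$group,
        transfers_a = a$transfers, implantations_a = a$implantations,
        rate_a = a$implantations / a$transfers,
        transfers_b = b$transfers, implantations_b = b$implantations,
        rate_b = b$implantations / b$transfers,
        p_value = fisher_exact_2x2(tab), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
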