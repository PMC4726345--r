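#' Simulation design for the synthetic endometrial study
#'
#' Parameters of the synthetic data generator. The defaults mirror the study
#' conditions the pipeline was built for: 43 RIF and 72 control samples across
#' three processing batches (cohort 1: 22 RIF / 23 control; cohort 2 batch 1:
#' 19 RIF / 45 control; cohort 2 batch 2: 2 RIF / 4 control), biopsy days
#' 5..8 after the LH surge in proportions 8/27/71/9, dye-swap profile pairs
#' against a common reference, a class effect on 100 genes of which 81% are
#' down-regulated in RIF, a RIF subgroup with control-like expression (20%
#' null, 20% intermediate at half effect), and per-transfer implantation
#' outcomes averaging 62.7% in controls and 3.2% in RIF.
#'
#' Effect size (`effect_size_delta`), noise and shift scales, and gene-set
#' counts are generator defaults chosen to give the pipeline realistic but
#' recoverable structure; they are not estimates of the real biology.
#'
#' @param n_genes number of probes (one probe per gene, a small fraction
#'   unannotated).
#' @param n_rif,n_control group sizes.
#' @param n_signature_genes genes carrying the class effect.
#' @param effect_size_delta class effect, log2 units, for a typical RIF sample.
#' @param frac_down fraction of affected genes down-regulated in RIF.
#' @param noise_sd median per-gene residual SD, log2 units (per-gene SDs are
#'   log-normal around this so the variability filter has a spread to act on).
#' @param noise_sdlog log-SD of the per-gene SD distribution.
#' @param batch_shifts SD of per-gene shifts for each non-reference batch.
#' @param day_effect_sd SD of per-gene shifts for each non-reference biopsy day.
#' @param frac_null_rif fraction of RIF samples with no expression effect.
#' @param frac_intermediate_rif fraction of RIF samples at half effect.
#' @param implantation_rate_control per-transfer implantation probability,
#'   controls.
#' @param implantation_rate_rif mean per-transfer implantation probability
#'   across RIF samples; the intermediate subtype gets
#'   `intermediate_rate_ratio` times the typical/null subtype rate, scaled so
#'   the RIF-wide expectation equals this value.
#' @param intermediate_rate_ratio relative implantation rate of the
#'   intermediate subtype.
#' @param transfers_per_sample inclusive range of embryo-transfer counts.
#' @param frac_low_intensity fraction of probes whose median intensity falls
#'   below the filtering cutoff.
#' @param frac_unannotated fraction of probes without a gene symbol.
#' @param n_gene_sets,planted_enriched_sets gene-set collection size and
#'   number of sets planted to be enriched in affected genes.
#' @param set_size_range inclusive range of gene-set sizes.
#' @param dye_swap_noise_sd independent per-profile noise, log2 units.
#' @param seed integer seed for the generator.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 2000L, n_rif = 43L, n_control = 72L,
                              n_signature_genes = 100L,
                              effect_size_delta = 0.7, frac_down = 0.81,
                              noise_sd = 0.4, noise_sdlog = 0.5,
                              batch_shifts = 0.3, day_effect_sd = 0.2,
                              frac_null_rif = 0.2,
                              frac_intermediate_rif = 0.2,
                              implantation_rate_control = 0.627,
                              implantation_rate_rif = 0.032,
                              intermediate_rate_ratio = 4,
                              transfers_per_sample = c(1L, 12L),
                              frac_low_intensity = 0.25,
                              frac_unannotated = 0.02,
                              n_gene_sets = 40L, planted_enriched_sets = 3L,
                              set_size_range = c(10L, 50L),
                              dye_swap_noise_sd = 0.1, seed = 1L) {
  stopifnot(n_signature_genes <= n_genes,
            frac_down >= 0, frac_down <= 1,
            frac_null_rif >= 0, frac_intermediate_rif >= 0,
            frac_null_rif + frac_intermediate_rif <= 1,
            implantation_rate_control >= 0, implantation_rate_control <= 1,
            implantation_rate_rif >= 0, implantation_rate_rif <= 1,
            frac_low_intensity >= 0, frac_low_intensity < 1,
            planted_enriched_sets <= n_gene_sets,
            transfers_per_sample[1] >= 0,
            transfers_per_sample[1] <= transfers_per_sample[2])
  structure(as.list(environment()), class = "simulation_design")
}

# Batch/day/center layout matching the study's recruitment structure.
assign_layout <- function(design) {
  n_rif <- design$n_rif
  n_ctl <- design$n_control
  n <- n_rif + n_ctl
  # Split each class over batches in the study's proportions
  # (RIF 22/19/2 of 43, control 23/45/4 of 72), rescaled for other sizes.
  split_counts <- function(total, props) {
    k <- floor(total * props)
    rem <- total - sum(k)
    if (rem > 0) {
      extra <- order(total * props - k, decreasing = TRUE)[seq_len(rem)]
      k[extra] <- k[extra] + 1L
    }
    k
  }
  rif_b <- split_counts(n_rif, c(22, 19, 2) / 43)
  ctl_b <- split_counts(n_ctl, c(23, 45, 4) / 72)
  batches <- c("c1", "c2b1", "c2b2")
  sheet <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    class_label = c(rep("RIF", n_rif), rep("control", n_ctl)),
    batch = c(rep(batches, rif_b), rep(batches, ctl_b)),
    stringsAsFactors = FALSE)
  sheet$cohort <- ifelse(sheet$batch == "c1", 1L, 2L)
  # Center B (the minor center) only recruited in cohort 2; ~9 of 115.
  coh2 <- which(sheet$cohort == 2L)
  n_b <- min(length(coh2), round(9 / 115 * n))
  sheet$center <- "A"
  sheet$center[sample(coh2, n_b)] <- "B"
  # Biopsy day frequencies 8/27/71/9 over days 5..8, allocated within each
  # class x batch cell so every recruitment stratum spans the day range and
  # the timing model is estimable on its designated control subset.
  sheet$biopsy_day <- NA_integer_
  for (cell in split(seq_len(n), paste(sheet$class_label, sheet$batch))) {
    d <- rep(5:8, times = split_counts(length(cell), c(8, 27, 71, 9) / 115))
    sheet$biopsy_day[cell] <- sample(d)
  }
  sheet
}

#' Generate a synthetic dye-swap expression study
#'
#' Produces a dye-swap pair of profiles per sample (the reverse profile has
#' its fold-change sign flipped, each profile carries independent noise), a
#' sample sheet with batch/day/center structure and per-transfer implantation
#' outcomes, a gene-set collection with planted enriched sets, and a truth
#' record of everything planted.
#'
#' Model, per gene g and sample s, on the log2 fold-change scale:
#' `M[g,s] = mu_g + batch_shift[g, batch(s)] + day_shift[g, day(s)] +
#' effect[g] * subtype_multiplier(s) + eps`, with `eps ~ N(0, sd_g)` and
#' per-gene `sd_g` log-normal around `noise_sd`. RIF subtypes multiply the
#' class effect by 1 (typical), 1/2 (intermediate) or 0 (null, control-like
#' expression). Affected genes are chosen among probes that pass the
#' intensity filter and have above-median baseline variability, so planted
#' signal is detectable by construction. `round(frac_down * n_signature_genes)`
#' of them carry a negative (down-in-RIF) sign.
#'
#' @param design a [simulation_design()].
#' @return A list with elements `profiles` (an `expression_dataset` of
#'   dye-swap profile pairs, columns `<sample>.F` / `<sample>.R`), `pairs`
#'   (data.frame sample_id, fwd, rev), `sheet` (a `rif_sample_sheet`), `sets`
#'   (a `gene_set_collection`), and `truth` (planted genes, signs, per-gene
#'   effects, subtype labels, batch/day shift matrices, enriched set ids).
#' @export
generate_dataset <- function(design) {
  set.seed(design$seed)
  ng <- design$n_genes
  probe_ids <- sprintf("P%05d", seq_len(ng))
  gene_ids <- sprintf("G%05d", seq_len(ng))
  n_unann <- round(design$frac_unannotated * ng)
  if (n_unann > 0) gene_ids[sample(ng, n_unann)] <- NA_character_

  sheet <- assign_layout(design)
  n <- nrow(sheet)

  # Baseline: per-gene mean fold change and log-normal per-gene noise SD.
  mu_g <- stats::rnorm(ng, 0, 0.25)
  sd_g <- stats::rlnorm(ng, meanlog = log(design$noise_sd),
                        sdlog = design$noise_sdlog)

  # Intensities: a fixed fraction of probes sit below the filter cutoff.
  n_low <- round(design$frac_low_intensity * ng)
  low_probes <- sample(ng, n_low)
  base_int <- stats::rnorm(ng, 9, 1.2)
  base_int[low_probes] <- stats::rnorm(n_low, 5, 0.4)

  # Class effect: planted on detectable probes (above-median intensity and
  # above-median baseline SD), with the configured down-regulated fraction.
  eligible <- setdiff(which(sd_g > stats::median(sd_g)), low_probes)
  if (length(eligible) < design$n_signature_genes) {
    stop("not enough detectable probes to plant the signature")
  }
  affected <- sort(sample(eligible, design$n_signature_genes))
  n_down <- round(design$frac_down * design$n_signature_genes)
  signs <- c(rep(-1, n_down), rep(1, design$n_signature_genes - n_down))
  signs <- signs[sample.int(length(signs))]
  effect <- numeric(ng)
  effect[affected] <- signs * design$effect_size_delta

  # RIF subtypes: null (no effect), intermediate (half), typical (full).
  n_null <- round(design$frac_null_rif * design$n_rif)
  n_int <- round(design$frac_intermediate_rif * design$n_rif)
  subtype <- rep("typical", design$n_rif)
  subtype[sample(design$n_rif, n_null + n_int)] <-
    c(rep("null", n_null), rep("intermediate", n_int))
  multiplier <- ifelse(sheet$class_label == "RIF",
                       c(typical = 1, intermediate = 0.5,
                         null = 0)[subtype[cumsum(sheet$class_label == "RIF")]],
                       0)

  # Per-gene batch and day shifts; c2b1 and day 7 are the reference levels.
  batch_shift <- cbind(c1 = stats::rnorm(ng, 0, design$batch_shifts),
                       c2b1 = 0,
                       c2b2 = stats::rnorm(ng, 0, design$batch_shifts))
  day_shift <- cbind(`5` = stats::rnorm(ng, 0, design$day_effect_sd),
                     `6` = stats::rnorm(ng, 0, design$day_effect_sd),
                     `7` = 0,
                     `8` = stats::rnorm(ng, 0, design$day_effect_sd))

  true_m <- matrix(mu_g, ng, n) +
    batch_shift[, sheet$batch] +
    day_shift[, as.character(sheet$biopsy_day)] +
    outer(effect, multiplier)
  noise <- matrix(stats::rnorm(ng * n, 0, sd_g), ng, n)
  m <- true_m + noise

  # Dye-swap pair per sample: independent profile noise; the reverse profile
  # is reference-over-sample oriented (sign flipped).
  eps_f <- matrix(stats::rnorm(ng * n, 0, design$dye_swap_noise_sd), ng, n)
  eps_r <- matrix(stats::rnorm(ng * n, 0, design$dye_swap_noise_sd), ng, n)
  m_f <- m + eps_f
  m_r <- -m + eps_r
  int_jit <- function() matrix(stats::rnorm(ng * n, 0, 0.2), ng, n)
  a_f <- matrix(base_int, ng, n) + int_jit()
  a_r <- matrix(base_int, ng, n) + int_jit()

  prof_ids <- c(rbind(paste0(sheet$sample_id, ".F"),
                      paste0(sheet$sample_id, ".R")))
  mm <- matrix(0, ng, 2 * n)
  aa <- matrix(0, ng, 2 * n)
  mm[, seq(1, 2 * n, 2)] <- m_f; mm[, seq(2, 2 * n, 2)] <- m_r
  aa[, seq(1, 2 * n, 2)] <- a_f; aa[, seq(2, 2 * n, 2)] <- a_r
  profiles <- expression_dataset(probe_ids, gene_ids, mm, aa, prof_ids)
  pairs <- data.frame(sample_id = sheet$sample_id,
                      fwd = paste0(sheet$sample_id, ".F"),
                      rev = paste0(sheet$sample_id, ".R"),
                      stringsAsFactors = FALSE)

  # Implantation outcomes: Bernoulli per transfer at the group rate. RIF
  # subtype rates keep the RIF-wide expectation at implantation_rate_rif
  # with the intermediate subtype at intermediate_rate_ratio times the rest.
  rng <- design$transfers_per_sample
  sheet$n_transfers <- sample(rng[1]:rng[2], n, replace = TRUE)
  n_typ <- design$n_rif - n_null - n_int
  r_low <- design$implantation_rate_rif * design$n_rif /
    (n_typ + n_null + design$intermediate_rate_ratio * n_int)
  r_low <- min(r_low, 1)
  rate <- ifelse(sheet$class_label == "control",
                 design$implantation_rate_control, r_low)
  rif_rows <- which(sheet$class_label == "RIF")
  rate[rif_rows[subtype == "intermediate"]] <-
    min(design$intermediate_rate_ratio * r_low, 1)
  sheet$n_implantations <- stats::rbinom(n, sheet$n_transfers, rate)
  sheet$split <- "unassigned"

  # Gene sets over annotated genes; planted sets draw most members from
  # affected genes so the enrichment stage has known positives.
  universe <- gene_ids[!is.na(gene_ids)]
  affected_genes <- gene_ids[affected]
  affected_genes <- affected_genes[!is.na(affected_genes)]
  sets <- list()
  planted_ids <- character(0)
  for (k in seq_len(design$n_gene_sets)) {
    id <- sprintf("SET%03d", k)
    sz <- sample(design$set_size_range[1]:design$set_size_range[2], 1)
    if (k <= design$planted_enriched_sets && length(affected_genes) >= 2) {
      n_aff <- min(length(affected_genes), ceiling(0.8 * sz))
      members <- unique(c(sample(affected_genes, n_aff),
                          sample(universe, sz - n_aff)))
      planted_ids <- c(planted_ids, id)
      desc <- "planted enriched set (synthetic)"
    } else {
      members <- unique(sample(universe, sz))
      desc <- "random set (synthetic)"
    }
    sets[[id]] <- list(description = desc, genes = members)
  }

  truth <- list(
    affected_probes = probe_ids[affected],
    affected_genes = gene_ids[affected],
    signs = signs,
    effect = stats::setNames(effect, probe_ids),
    subtype = stats::setNames(subtype, sheet$sample_id[rif_rows]),
    batch_shift = `rownames<-`(batch_shift, probe_ids),
    day_shift = `rownames<-`(day_shift, probe_ids),
    low_intensity_probes = probe_ids[low_probes],
    planted_sets = planted_ids,
    implantation_rate_by_subtype = c(typical = r_low, null = r_low,
                                     intermediate = min(design$intermediate_rate_ratio * r_low, 1)))

  list(profiles = profiles, pairs = pairs, sheet = sample_sheet(sheet),
       sets = gene_set_collection(sets), truth = truth)
}

#' Generate a null dataset with no class, batch, or day structure
#'
#' Same sampling scheme as [generate_dataset()] but every planted effect
#' (class, batch, biopsy day) is zero, so class labels are exchangeable with
#' expression by construction. Used to calibrate the discovery and
#' enrichment stages.
#'
#' @param design a [simulation_design()].
#' @return Same structure as [generate_dataset()].
#' @export
generate_null_dataset <- function(design) {
  design$effect_size_delta <- 0
  design$batch_shifts <- 0
  design$day_effect_sd <- 0
  generate_dataset(design)
}
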