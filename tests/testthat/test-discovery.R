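test_that("splitting stratifies by class and is deterministic", {
  study <- generate_dataset(simulation_design(seed = 41))
  sp <- split_samples(study$sheet, 81, seed = 9)
  expect_length(sp$discovery_ids, 81)
  expect_length(sp$validation_ids, 34)
  expect_length(intersect(sp$discovery_ids, sp$validation_ids), 0)
  rif <- study$sheet$sample_id[study$sheet$class_label == "RIF"]
  expect_true(sum(sp$discovery_ids %in% rif) %in% c(30, 31))
  sp2 <- split_samples(study$sheet, 81, seed = 9)
  expect_identical(sp, sp2)
  one <- tiny_sheet(paste0("S", 1:6), rep("RIF", 6))
  expect_error(split_samples(one, 4), "each class")
})

test_that("signal-to-noise matches hand arithmetic and a brute-force oracle", {
  expect_equal(signal_to_noise(c(1, 2, 3), c(4, 5, 6)), -1.5)
  expect_equal(signal_to_noise(c(2, 4), c(1, 5)), 0)
  expect_warning(s <- signal_to_noise(c(1, 1), c(2, 2)), "degenerate")
  expect_equal(s, 0)
  expect_error(signal_to_noise(1, c(1, 2)), ">= 2 samples")

  set.seed(12)
  m <- matrix(rnorm(100 * 20), 100, 20,
              dimnames = list(sprintf("P%03d", 1:100), NULL))
  is_rif <- rep(c(TRUE, FALSE), each = 10)
  fast <- rifsignature:::snr_matrix(m, is_rif)
  slow <- apply(m, 1, function(v) {
    (mean(v[is_rif]) - mean(v[!is_rif])) / (sd(v[is_rif]) + sd(v[!is_rif]))
  })
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("resampling rounds are deterministic and recover planted probes", {
  study <- generate_dataset(small_design(43))
  prep <- preprocess_study(study)
  sheet <- study$sheet
  cfg <- pipeline_config(n_rounds = 30L, rng_seed = 43)
  filt <- filter_probes(prep$dataset, sheet$sample_id)
  r1 <- run_resampling(filt$dataset, sheet, cfg, seed = 7)
  r2 <- run_resampling(filt$dataset, sheet, cfg, seed = 7)
  expect_identical(r1[[1]]$ranked_probe_ids, r2[[1]]$ranked_probe_ids)
  expect_identical(r1[[30]]$test_scores, r2[[30]]$test_scores)
  for (r in r1) {
    expect_length(intersect(r$train_ids, r$test_ids), 0)
    expect_length(r$ranked_probe_ids, cfg$n_top_genes)
    expect_true(all(r$test_scores$score >= 0 & r$test_scores$score <= 1))
  }
  # planted probes are ranked far more often than null probes
  counts <- aggregate_signature(r1, min_frequency = 1)$counts
  all_counts <- setNames(numeric(length(filt$dataset$probe_ids)),
                         filt$dataset$probe_ids)
  all_counts[names(counts)] <- counts
  planted <- intersect(study$truth$affected_probes, names(all_counts))
  mw <- wilcox.test(all_counts[planted],
                    all_counts[setdiff(names(all_counts), planted)],
                    alternative = "greater", exact = FALSE)
  expect_lt(mw$p.value, 1e-6)
})

test_that("signature aggregation thresholds inclusively and shrinks monotonically", {
  rounds <- list(
    list(ranked_probe_ids = c("A", "B")),
    list(ranked_probe_ids = c("A", "B")),
    list(ranked_probe_ids = c("A", "B")),
    list(ranked_probe_ids = c("A", "B", "C")),
    list(ranked_probe_ids = c("A", "B", "C")),
    list(ranked_probe_ids = c("A", "C")),
    list(ranked_probe_ids = c("A", "C")),
    list(ranked_probe_ids = c("A")),
    list(ranked_probe_ids = c("A")),
    list(ranked_probe_ids = c("A")))
  # counts: A=10, B=5, C=4; the threshold is inclusive
  sig5 <- aggregate_signature(rounds, min_frequency = 5)
  expect_setequal(sig5$selected_probes, c("A", "B"))
  sig6 <- aggregate_signature(rounds, min_frequency = 6)
  expect_setequal(sig6$selected_probes, c("A"))
  sig1 <- aggregate_signature(rounds, min_frequency = 1)
  expect_setequal(sig1$selected_probes, c("A", "B", "C"))
  # monotone shrinkage
  prev <- sig1$selected_probes
  for (k in 2:11) {
    cur <- aggregate_signature(rounds, min_frequency = k)$selected_probes
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_warning(aggregate_signature(rounds, min_frequency = 11), "empty")
  # unannotated probes count as their own gene
  sig <- aggregate_signature(rounds, 5,
                             gene_map = c(A = "G1", B = NA, C = "G2"))
  expect_setequal(sig$selected_probes, c("A", "B"))
  expect_setequal(sig$selected_genes, c("G1", "B"))
})

test_that("the classifier separates separable data and behaves symmetrically", {
  ids <- paste0("S", 1:8)
  m <- rbind(P1 = c(1, 1.2, 0.8, 1.1, -1, -1.2, -0.8, -1.1),
             P2 = c(0.9, 1.1, 1.0, 1.3, -0.9, -1.1, -1.0, -1.3))
  colnames(m) <- ids
  ds <- tiny_dataset(m)
  y <- c(rep("RIF", 4), rep("control", 4))
  sheet <- tiny_sheet(ids, y)
  model <- train_classifier(ds, sheet, c("P1", "P2"))
  sc <- score_samples(model, ds)
  expect_true(all(sc$score[y == "RIF"] >= 0.5))
  expect_true(all(sc$score[y == "control"] < 0.5))
  expect_true(all(sc$score >= 0 & sc$score <= 1))

  # boundary rule: a score exactly at the threshold calls RIF
  sc_at <- score_samples(model, ds, threshold = sc$score[1])
  expect_equal(sc_at$call[1], "RIF")

  # flipped labels give complementary scores (noisy, non-separable data)
  set.seed(8)
  m2 <- m + matrix(rnorm(16, sd = 1.5), 2)
  colnames(m2) <- ids
  ds2 <- tiny_dataset(m2)
  sheet_flip <- tiny_sheet(ids, ifelse(y == "RIF", "control", "RIF"))
  s_orig <- score_samples(train_classifier(ds2, sheet, c("P1", "P2")), ds2)
  s_flip <- score_samples(train_classifier(ds2, sheet_flip, c("P1", "P2")),
                          ds2)
  expect_equal(s_flip$score, 1 - s_orig$score, tolerance = 1e-6)

  # determinism and constant-feature handling
  m3 <- rbind(m, P3 = rep(2, 8))
  ds3 <- tiny_dataset(m3)
  expect_warning(model3 <- train_classifier(ds3, sheet, c("P1", "P2", "P3")),
                 "constant feature")
  expect_equal(model3$probes, c("P1", "P2"))
  expect_identical(train_classifier(ds, sheet, c("P1", "P2"))$calibration,
                   model$calibration)
  expect_error(train_classifier(ds, sheet, "NOPE"), "absent")
  expect_error(score_samples(model, subset_dataset(ds, probes = "P1")),
               "missing probe")
})

test_that("LOOCV trains one model per sample and scores each once", {
  study <- generate_dataset(small_design(47))
  prep <- preprocess_study(study)
  ids <- study$sheet$sample_id[c(1:6, 50:59)]
  ds <- subset_dataset(prep$dataset, samples = ids)
  probes <- study$truth$affected_probes[1:10]
  out <- loocv(ds, study$sheet, probes)
  expect_equal(out$sample_id, ids)
  expect_equal(anyDuplicated(out$sample_id), 0)
  expect_true(all(out$score >= 0 & out$score <= 1))
  out2 <- loocv(ds, study$sheet, probes)
  expect_identical(out, out2)
})

test_that("validation refuses leaked samples and is reproducible", {
  study <- generate_dataset(small_design(53))
  prep <- preprocess_study(study)
  sp <- split_samples(study$sheet, 81, seed = 3)
  bad <- sp
  bad$validation_ids <- c(bad$validation_ids, bad$discovery_ids[1])
  expect_error(validate_signature(prep$dataset, study$sheet, bad,
                                  study$truth$affected_probes[1:10]),
               "leakage")
  v1 <- validate_signature(prep$dataset, study$sheet, sp,
                           study$truth$affected_probes[1:10])
  expect_equal(nrow(v1), 34)
  expect_identical(v1, validate_signature(prep$dataset, study$sheet, sp,
                                          study$truth$affected_probes[1:10]))
})
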