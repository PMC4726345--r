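test_that("effect estimation is the group-mean contrast (closed-form OLS)", {
  ids <- paste0("S", 1:8)
  day <- c(7, 7, 7, 7, 6, 6, 6, 6)
  m <- rbind(P1 = ifelse(day == 6, 0.5, 0.0),
             P2 = ifelse(day == 6, -1.25, 0.0) + 2)
  colnames(m) <- ids
  ds <- tiny_dataset(m)
  sheet <- tiny_sheet(ids, rep("control", 8), day = day)
  mod <- estimate_effect(ds, sheet, "biopsy_day", ids, reference_level = "7")
  expect_equal(unname(mod$coefficients[, "6"]), c(0.5, -1.25))
  expect_equal(mod$reference_level, "7")
  expect_equal(mod$estimation_sample_ids, ids)

  # a level with <2 samples is fatal, naming the level
  sheet2 <- tiny_sheet(ids, rep("control", 8), day = c(7, 7, 7, 7, 6, 6, 6, 5))
  expect_error(estimate_effect(ds, sheet2, "biopsy_day", ids,
                               reference_level = "7"), "5")
  expect_error(estimate_effect(ds, tiny_sheet(ids, rep("control", 8)),
                               "biopsy_day", ids), "constant")
  expect_error(estimate_effect(ds, sheet, "biopsy_day", character(0)),
               "empty")
})

test_that("shuffled (null) covariate yields coefficients centered on zero", {
  set.seed(4)
  ids <- paste0("S", 1:40)
  m <- matrix(rnorm(200 * 40), 200, 40,
              dimnames = list(sprintf("P%03d", 1:200), ids))
  sheet <- tiny_sheet(ids, rep("control", 40),
                      day = sample(c(6, 7), 40, replace = TRUE))
  mod <- estimate_effect(tiny_dataset(m), sheet, "biopsy_day", ids,
                         reference_level = "7")
  co <- mod$coefficients[, "6"]
  expect_lt(abs(mean(co)), 3 * sd(co) / sqrt(length(co)))
})

test_that("planted batch and day shifts are recovered within 3 SE", {
  study <- generate_dataset(simulation_design(seed = 23))
  prep0 <- preprocess_study(study, correct_day = FALSE, correct_batch = FALSE)
  dataset <- prep0$dataset
  sheet <- study$sheet
  controls <- sheet$sample_id[sheet$class_label == "control"]
  mod <- estimate_effect(dataset, sheet, "batch", controls,
                         reference_level = "c2b1")
  for (lev in c("c1", "c2b2")) {
    z <- (mod$coefficients[, lev] - study$truth$batch_shift[, lev]) /
      mod$stderr[, lev]
    expect_lt(mean(abs(z)), 3)
  }
  timing <- sheet$sample_id[sheet$batch == "c2b1" &
                              sheet$class_label == "control"]
  modd <- estimate_effect(dataset, sheet, "biopsy_day", timing,
                          reference_level = "7")
  for (lev in c("5", "6", "8")) {
    z <- (modd$coefficients[, lev] - study$truth$day_shift[, lev]) /
      modd$stderr[, lev]
    expect_lt(mean(abs(z)), 3)
  }
})

test_that("correction subtracts coefficients, is invertible, and re-estimates to zero", {
  ids <- paste0("S", 1:8)
  day <- c(7, 7, 7, 7, 6, 6, 5, 5)
  m <- matrix(rnorm(40), 5, 8, dimnames = list(sprintf("P%d", 1:5), ids))
  shift6 <- rnorm(5); shift5 <- rnorm(5)
  m2 <- m
  m2[, day == 6] <- m2[, day == 6] + shift6
  m2[, day == 5] <- m2[, day == 5] + shift5
  ds <- tiny_dataset(m2)
  sheet <- tiny_sheet(ids, rep("control", 8), day = day)
  mod <- estimate_effect(ds, sheet, "biopsy_day", ids, reference_level = "7")
  corr <- apply_correction(ds, mod, sheet)
  # reference-level samples unchanged
  expect_equal(corr$m_values[, day == 7], m2[, day == 7])
  # noise-free planted shift: re-estimation on corrected data ~ 0
  mod2 <- estimate_effect(corr, sheet, "biopsy_day", ids,
                          reference_level = "7")
  expect_lt(max(abs(mod2$coefficients)), 1e-8)
  # exactly invertible
  back <- corr
  for (lev in colnames(mod$coefficients)) {
    idx <- which(day == as.numeric(lev))
    back$m_values[, idx] <- back$m_values[, idx] + mod$coefficients[, lev]
  }
  expect_equal(back$m_values, ds$m_values)
  # zero-coefficient model is the identity
  mod0 <- mod; mod0$coefficients[] <- 0
  expect_equal(apply_correction(ds, mod0, sheet)$m_values, ds$m_values)
  # unknown level is fatal
  sheet$biopsy_day[1] <- 8L
  expect_error(apply_correction(ds, mod, sheet), "absent from model")
})

test_that("pca_qc reports sane variance and detects then clears batch structure", {
  study <- generate_dataset(simulation_design(seed = 29))
  raw <- merge_dye_swaps(study$profiles, study$pairs)
  qc_before <- pca_qc(raw, study$sheet, covariates = "batch",
                      n_components = 2)
  ve <- qc_before$variance_explained
  expect_true(all(diff(ve) <= 0))
  expect_lte(sum(ve), 1)
  expect_lt(min(qc_before$associations$p_value), 0.05 / 2)

  prep <- preprocess_study(study)
  qc_after <- pca_qc(prep$dataset, study$sheet, covariates = "batch",
                     n_components = 2)
  expect_gt(min(qc_after$associations$p_value) * 2, 0.05)

  expect_error(pca_qc(subset_dataset(raw, samples = 1:2), study$sheet),
               "3 samples")
})
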