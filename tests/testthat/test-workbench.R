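test_that("trace text and binary containers round trip", {
  set.seed(1)
  tr <- as_trace(rnorm(500, -100, 2), 20000, voltage = -50,
                 metadata = list(pore = "WT AeL", kcl_m = 4))
  txt <- tempfile(fileext = ".txt")
  write_trace(tr, txt)
  back <- read_trace(txt)
  expect_equal(back$samples, tr$samples, tolerance = 1e-12)
  expect_equal(back$sampling_rate, tr$sampling_rate)
  expect_equal(back$voltage, tr$voltage)
  expect_equal(back$metadata$kcl_m, 4)

  bin <- tempfile(fileext = ".rds")
  write_trace(tr, bin, format = "binary")
  expect_equal(read_trace(bin, format = "binary"), tr)

  # corrupted header errors with a parse message
  lines <- readLines(txt)
  writeLines(lines[-1], txt)
  expect_error(read_trace(txt), "sampling_rate_hz")
  writeLines(c(lines[1:3], "not-a-number", lines[-(1:3)]), txt)
  expect_error(read_trace(txt), "malformed")
})

test_that("event and feature tables round trip with all columns", {
  pt <- pulse_trace(n_pulses = 6, noise_sd = 2, seed = 5)
  ev <- detect_events(pt$trace)
  f <- tempfile(fileext = ".tsv")
  write_event_table(ev, f)
  expect_equal(read_event_table(f), ev, tolerance = 1e-12)

  ft <- extract_features(ev, pt$trace, i0 = -100)
  ft$label <- "C2"
  f2 <- tempfile(fileext = ".tsv")
  write_feature_table(ft, f2)
  back <- read_feature_table(f2)
  expect_equal(back[feature_names()], ft[feature_names()],
               tolerance = 1e-10)
  expect_equal(ncol(back), 43 + 3)   # event_id, batch, label

  # missing feature column is named in the error
  broken <- ft[, setdiff(names(ft), "hskew@lp500")]
  write.table(broken, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_feature_table(f2), "hskew@lp500")

  expect_true(io_round_trip(ev))
})

test_that("the feature library records provenance and recovers Gaussians", {
  lib <- build_default_library(pfca_analytes(c("C2", "C5", "C9")))
  vm <- fit_volume_blockade(
    lib$volume, lib$blockade_mean,
    labels = lib$label)
  flib0 <- build_feature_library(vm, lib)
  expect_true(all(flib0$provenance == "predicted"))
  # predicted blockade mean propagates from the volume model
  expect_equal(unname(flib0$mean[, "blockade@lp2000"]), lib$blockade_mean,
               tolerance = 1e-6)

  # with data: moment fits within 3 sigma / sqrt(n)
  gen <- default_feature_library(lib)
  n <- 300
  tb <- simulate_feature_table(gen, n, seed = 7)
  flib1 <- build_feature_library(vm, lib, feature_table = tb)
  expect_true(all(flib1$provenance == "fitted"))
  for (f in c("tau_on", "isd@lp500", "hfwhm@lp100")) {
    expect_lt(max(abs(flib1$mean[, f] - gen$mean[, f]) / gen$sd[, f]),
              4 / sqrt(n))
  }
  expect_error(build_feature_library(vm, data.frame(label = "X")), "volume")
})

test_that("the pipeline runs end to end and is deterministic under seed", {
  lib <- build_default_library(pfca_analytes(c("C2", "C5", "C9")),
                               concentration = 4e-6)
  cfg <- run_config(sim_config(lib, duration = 12), seed = 5,
                    classifier_train_n = 80,
                    classifier = bag_config(ntree = 30, folds = 3))
  rep1 <- run_pipeline(cfg)
  expect_s3_class(rep1, "pipeline_report")
  expect_lt(abs(rep1$baseline$i0 - (-100)), 1)
  expect_gt(nrow(rep1$events), 10)
  # identified counts match ground truth per analyte within a few events
  truth_counts <- table(rep1$truth$label)
  est_counts <- setNames(rep1$interval_stats$count,
                         rep1$interval_stats$label)
  for (l in names(truth_counts))
    expect_lte(abs(est_counts[[l]] - truth_counts[[l]]),
               max(3, 0.2 * truth_counts[[l]]))

  rep2 <- run_pipeline(cfg)
  expect_identical(rep1$concentrations, rep2$concentrations)
  expect_identical(rep1$identification, rep2$identification)
})

test_that("pipeline concentrations bracket the simulated truth", {
  lib <- build_default_library(pfca_analytes(c("C2", "C9")),
                               concentration = 6e-6)
  cfg <- run_config(sim_config(lib, duration = 25), seed = 11,
                    classifier_train_n = 60,
                    classifier = bag_config(ntree = 25, folds = 3))
  rep <- run_pipeline(cfg)
  cc <- rep$concentrations
  hits <- vapply(c("C2", "C9"), function(l) {
    row <- cc[cc$label == l, ]
    row$ci_lo <= 6e-6 && 6e-6 <= row$ci_hi
  }, logical(1))
  expect_gte(sum(hits), 1)
  # point estimates are the right order of magnitude
  expect_true(all(abs(log10(cc$concentration / 6e-6)) < 0.3))
})

test_that("flagged-unknown events are never counted as PFCAs", {
  lib <- build_default_library(pfca_analytes(c("C2", "C5", "C9")),
                               concentration = 4e-6)
  # spike a probe-tethered fatty acid: C5-like blockade, 8x dwell
  fat <- lib[2, ]
  fat$label <- "FAT"
  fat$dwell_log_mean <- fat$dwell_log_mean + log(8)
  fat$concentration <- 8e-6
  tr <- simulate_trace(sim_config(rbind(lib, fat), duration = 15,
                                  seed = 77))
  # identification library knows only the three PFCAs
  cfg <- run_config(sim_config(lib, duration = 15), seed = 9,
                    classifier_train_n = 60,
                    classifier = bag_config(ntree = 25, folds = 3))
  rep <- run_pipeline(cfg, trace = tr$trace)
  flagged <- rep$identification$method == "flagged-unknown"
  # every flagged event is excluded from identification labels
  expect_true(all(is.na(rep$identification$label[flagged])))
  # most fatty-acid events (long dwell) get flagged, not counted as PFCA
  n_fat_truth <- sum(tr$truth$label == "FAT")
  expect_gt(n_fat_truth, 3)
  expect_gt(sum(flagged), 0.5 * n_fat_truth)
  # counted events roughly match the PFCA-only truth
  n_pfca_truth <- sum(tr$truth$label != "FAT")
  n_counted <- sum(rep$interval_stats$count)
  expect_lt(abs(n_counted - n_pfca_truth), max(4, 0.3 * n_pfca_truth))
})

test_that("an internal standard recalibrates the capture constant", {
  # recording produced with the true (unknown to the analyst) k = 3e5
  lib_true <- build_default_library(pfca_analytes(c("C2", "C6", "C9")),
                                    concentration = 5e-6,
                                    capture_constant = 3e5)
  tr <- simulate_trace(sim_config(lib_true, duration = 30, seed = 41))$trace

  # analysis config claims a wrong k but declares the C6 standard
  lib_wrong <- lib_true
  lib_wrong$capture_constant <- 1e5
  sim_std <- sim_config(lib_wrong, duration = 30,
                        internal_standard = list(label = "C6",
                                                 concentration = 5e-6))
  cfg <- run_config(sim_std, seed = 13, classifier_train_n = 60,
                    classifier = bag_config(ntree = 25, folds = 3))
  with_std <- run_pipeline(cfg, trace = tr)
  c2_std <- with_std$concentrations$concentration[
    with_std$concentrations$label == "C2"]
  expect_lt(abs(log(c2_std / 5e-6)), log(1.8))

  # without the standard the wrong k propagates (3x overestimate)
  sim_no <- sim_config(lib_wrong, duration = 30)
  no_std <- run_pipeline(run_config(sim_no, seed = 13,
                                    classifier_train_n = 60,
                                    classifier = bag_config(ntree = 25,
                                                            folds = 3)),
                         trace = tr)
  c2_no <- no_std$concentrations$concentration[
    no_std$concentrations$label == "C2"]
  expect_gt(c2_no / 5e-6, 2)
})
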