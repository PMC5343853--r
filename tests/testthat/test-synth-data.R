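test_that("synth_config validates its fields", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(n_transcripts = 0), "positive count")
  expect_error(synth_config(enriched_fraction = 1.2), "proportion")
  expect_error(synth_config(fc_range = c(0.5, 4)), "lower bound > 1")
  expect_error(synth_config(conditions = c("LPS", "control")), "start with 'control'")
  expect_error(synth_config(efficiency = 2.5), "efficiency")
  expect_error(synth_config(reference_gene = ""), "reference_gene")
})

test_that("EST generator conserves counts and honours the plant", {
  cfg <- synth_config(n_transcripts = 8, n_est_per_library = 200,
                      enriched_fraction = 0.5, seed = 3)
  out <- generate_est_libraries(cfg)
  expect_equal(unname(table(out$ests$library)["bacterial"]), 200)
  expect_equal(unname(table(out$ests$library)["viral"]), 200)
  expect_equal(sum(out$truth$n_est_bacterial), 200)
  expect_equal(sum(out$truth$n_est_viral), 200)
  expect_equal(sum(out$truth$enriched_in != "none"), 4)

  # planted transcripts draw mostly from their home library
  enr <- out$truth[out$truth$enriched_in == "bacterial", ]
  frac <- enr$n_est_bacterial / (enr$n_est_bacterial + enr$n_est_viral)
  expect_true(all(frac > 0.75))

  none <- generate_est_libraries(synth_config(enriched_fraction = 0, seed = 1))
  expect_equal(sum(none$truth$enriched_in != "none"), 0)
})

test_that("EST generator output is byte-identical under a fixed seed", {
  cfg <- synth_config(n_transcripts = 5, n_est_per_library = 30, seed = 99)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_est_fasta(generate_est_libraries(cfg)$ests, f1)
  write_est_fasta(generate_est_libraries(cfg)$ests, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("array generator structure matches the configuration", {
  cfg <- synth_config(n_targets = 50, n_arrays_per_condition = 2,
                      single_probe_fraction = 0.2, spike_in_count = 4,
                      seed = 7)
  out <- generate_array_experiment(cfg)
  expect_equal(nrow(out$design), 6)
  # every target has 1 or 3 probes; spike-ins one probe each
  sizes <- table(out$probesets$target_id)
  expect_true(all(sizes %in% c(1L, 3L)))
  expect_equal(sum(grepl("^SPIKE", out$probesets$target_id)), 4)
  # full grid: every probe on every array
  expect_equal(nrow(out$spots), nrow(out$probesets) * nrow(out$design))
  expect_true(all(out$spots$SI >= 0 & out$spots$SB >= 0))
})

test_that("zero-noise arrays have identical probes within target and array", {
  cfg <- synth_config(n_targets = 30, noise_sd = 0, background_mean = 0,
                      background_sd = 0, seed = 2)
  out <- generate_array_experiment(cfg)
  one <- out$spots[out$spots$array_id == out$design$array_id[1], ]
  spread <- tapply(one$SI, one$target_id, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("de_fraction of zero gives an empty truth table", {
  out <- generate_array_experiment(
    synth_config(n_targets = 40, de_fraction_per_condition = 0, seed = 5))
  expect_equal(nrow(out$truth), 0)
})

test_that("planted exclusive/common structure is as configured", {
  cfg <- synth_config(n_targets = 1000, de_fraction_per_condition = 0.1,
                      common_fraction = 0.4, seed = 13)
  out <- generate_array_experiment(cfg)
  lps <- out$truth[out$truth$condition == "LPS", ]
  pgn <- out$truth[out$truth$condition == "PGN", ]
  expect_equal(nrow(lps), 100)
  expect_equal(nrow(pgn), 100)
  expect_equal(length(intersect(lps$target_id, pgn$target_id)), 40)
  expect_equal(sum(lps$exclusive), 60)
})

test_that("qPCR generator encodes planted fold changes in Cq space", {
  # planted FC = 8 with E = 2 and a flat reference shifts Cq by 3 cycles
  cfg <- synth_config(n_targets = 40, noise_sd = 0, seed = 4)
  truth <- data.frame(target_id = "G00001", condition = "LPS",
                      true_log2fc = 3, stringsAsFactors = FALSE)
  q <- generate_qpcr(cfg, truth)
  cq <- q$cq
  g_ctl <- mean(cq$Cq[cq$gene == "G00001" & cq$condition == "control"])
  g_lps <- mean(cq$Cq[cq$gene == "G00001" & cq$condition == "LPS"])
  expect_equal(g_ctl - g_lps, 3)
  r_ctl <- cq$Cq[cq$gene == "18S" & cq$condition == "control"]
  r_lps <- cq$Cq[cq$gene == "18S" & cq$condition == "LPS"]
  expect_equal(unique(c(r_ctl, r_lps)), 15)

  # determinism
  q2 <- generate_qpcr(cfg, truth)
  expect_identical(q$cq, q2$cq)
})

test_that("zero-noise qPCR round-trips through Pfaffl quantification", {
  cfg <- synth_config(n_targets = 200, noise_sd = 0, seed = 21)
  arr <- generate_array_experiment(cfg)
  q <- generate_qpcr(cfg, arr$truth)
  fc <- qpcr_fold_changes(q$cq, reference_gene = "18S")
  m <- merge(fc, q$truth, by.x = c("gene", "condition"),
             by.y = c("gene", "condition"))
  expect_equal(log2(m$ratio), m$true_log2fc, tolerance = 1e-12)
})

test_that("generators reject invalid inputs", {
  cfg <- synth_config(n_targets = 20, seed = 1)
  expect_error(generate_qpcr(cfg, NULL), "truth table")
  expect_error(generate_est_libraries(list()), "synth_config")
})
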