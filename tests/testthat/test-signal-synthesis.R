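test_that("pulse programs carry the published phase structure", {
  mrpv <- pulse_program_mrpv()
  mspv <- pulse_program_mspv()
  expect_equal(mrpv$phases$freq_hz, c(1, 10, 100))
  expect_equal(mrpv$phases$duration_s, c(11, 1.1, 0.11))
  expect_equal(program_duration(mrpv), 12.21)
  expect_equal(program_duration(mspv), 7.77)
  # floor rule: a 0.02 s interval gives 610 samples per electrode (610.5 down)
  expect_identical(pulse_sample_count(pulse_program_mrpv(0.02)), 610L)
  expect_error(pulse_program(data.frame(freq_hz = 1, duration_s = 1),
                             sampling_interval = 0), "positive")
})

test_that("e-nose trace has rise, plateau at the class amplitude, and decay", {
  spec <- age_class_spec(3, n_samples = 1,
                         channel_amplitudes = c(S10 = 2200), noise_sd = 0)
  tr <- simulate_enose_trace(spec, "S10", seed = 1)
  expect_length(tr$time_s, 231)
  expect_equal(range(tr$time_s), c(0, 230))
  # plateau: exactly the amplitude at t = 30 s, < 1% variation on [10, 50]
  expect_equal(tr$value[tr$time_s == 30], 2200)
  plateau <- tr$value[tr$time_s >= 10 & tr$time_s <= 50]
  expect_lt(diff(range(plateau)), 0.01 * 2200)
  # decay ends near baseline
  expect_lt(tr$value[tr$time_s == 230], 0.05 * 2200)
  # bounded
  expect_true(all(tr$value >= 0 & tr$value <= 3500))
})

test_that("zero-amplitude e-nose trace is flat at baseline", {
  spec <- age_class_spec(3, 1, channel_amplitudes = c(S1 = 0), noise_sd = 0)
  tr <- simulate_enose_trace(spec, "S1", seed = 1)
  expect_equal(tr$value, rep(0, 231))
})

test_that("unknown channels are rejected with the valid set named", {
  spec <- age_class_spec(3, 1, channel_amplitudes = c(S1 = 100), noise_sd = 0)
  expect_error(simulate_enose_trace(spec, "S13", seed = 1), "S1.*S12")
  expect_error(simulate_etongue_trace(spec, "E4", pulse_program_mrpv(), 1),
               "E1.*E3")
})

test_that("e-tongue trace length follows floor(duration / interval)", {
  spec <- age_class_spec(3, 1, noise_sd = 0)
  tr <- simulate_etongue_trace(spec, "E1", pulse_program_mrpv(0.02), seed = 1)
  expect_length(tr$value, 610)
  tr2 <- simulate_etongue_trace(spec, "E1", pulse_program_mrpv(), seed = 1)
  expect_length(tr2$value, 6105)
})

test_that("e-tongue transient collapses to steady-state levels as tau -> 0", {
  spec <- age_class_spec(3, 1, channel_amplitudes = c(E1 = 10), noise_sd = 0)
  prog <- pulse_program_mrpv(0.02)
  tr <- simulate_etongue_trace(spec, "E1", prog, seed = 1, tau = 1e-9,
                               iss_frac = 0.35)
  # only the steady-state currents of the two potential levels remain
  lv <- sort(unique(round(tr$value, 9)))
  expect_equal(lv, sort(0.35 * 10 * prog$potential_levels))
})

test_that("peak currents are ordered like the class analyte levels", {
  lo <- age_class_spec(3, 1, channel_amplitudes = c(E1 = 8), noise_sd = 0)
  hi <- age_class_spec(20, 1, channel_amplitudes = c(E1 = 14), noise_sd = 0)
  prog <- pulse_program_mspv(0.02)
  tr_lo <- simulate_etongue_trace(lo, "E1", prog, seed = 1)
  tr_hi <- simulate_etongue_trace(hi, "E1", prog, seed = 1)
  expect_gt(max(tr_hi$value), max(tr_lo$value))
  expect_true(all(tr_hi$value >= tr_lo$value - 1e-12))
})

test_that("simulation is deterministic under a fixed seed", {
  spec <- age_class_spec(5, 1, noise_sd = 0.05)
  t1 <- simulate_enose_trace(spec, "S3", seed = 42)
  t2 <- simulate_enose_trace(spec, "S3", seed = 42)
  expect_identical(t1, t2)
  d1 <- simulate_dataset(default_age_specs(2), seed = 9,
                         program_mrpv = fast_mrpv(), program_mspv = fast_mspv())
  d2 <- simulate_dataset(default_age_specs(2), seed = 9,
                         program_mrpv = fast_mrpv(), program_mspv = fast_mspv())
  expect_identical(d1, d2)
})

test_that("dataset has the design counts and labels", {
  d <- simulate_dataset(default_age_specs(2), seed = 3,
                        program_mrpv = fast_mrpv(), program_mspv = fast_mspv())
  expect_equal(nrow(d$labels), 10)               # 5 classes x 2
  expect_length(d$traces, 10 * 18)               # 6 e-tongue + 12 e-nose each
  expect_setequal(unique(d$labels$age_years), c(3, 5, 8, 10, 20))
  one <- simulate_dataset(default_age_specs(1), seed = 3,
                          program_mrpv = fast_mrpv(),
                          program_mspv = fast_mspv())
  expect_equal(nrow(one$labels), 5)
  expect_error(
    simulate_dataset(list(age_class_spec(3, 1), age_class_spec(3, 1)),
                     seed = 1),
    "duplicate")
})

test_that("default age spec invariants hold", {
  specs <- default_age_specs()
  expect_equal(vapply(specs, function(s) s$age_years, numeric(1)),
               c(3, 5, 8, 10, 20))
  expect_true(all(vapply(specs, function(s) s$n_samples, integer(1)) == 40L))
  expect_error(age_class_spec(3, n_samples = 0), "positive")
  expect_error(age_class_spec(3, channel_amplitudes = c(S1 = -1)), ">= 0")
})

test_that("noiseless features are linearly separable by class", {
  nl <- noiseless_tables()
  fused <- fuse(nl$etongue, nl$enose, fusion_spec("direct"))
  # nearest class centroid (a linear rule) classifies perfectly
  cls <- factor(fused$age_years)
  centroids <- apply(fused$features, 2, tapply, cls, mean)
  d <- as.matrix(dist(rbind(fused$features, centroids)))
  d <- d[seq_len(nrow(fused$features)), nrow(fused$features) + seq_len(nlevels(cls))]
  pred <- levels(cls)[apply(d, 1, which.min)]
  expect_equal(pred, as.character(cls))
})

test_that("trace CSV round-trips losslessly", {
  d <- simulate_dataset(default_age_specs(1), seed = 4,
                        program_mrpv = fast_mrpv(), program_mspv = fast_mspv())
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(d$traces[1:4], path)
  back <- read_traces_csv(path)
  expect_length(back, 4)
  expect_equal(back[[1]]$value, d$traces[[1]]$value)
  expect_equal(back[[1]]$channel_id, d$traces[[1]]$channel_id)
})
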