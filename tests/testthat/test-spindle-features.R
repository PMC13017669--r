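# Spindle and slow-oscillation detection, and the 10-feature summary.

test_that("a single injected burst is detected once with correct frequency", {
  fx <- fx_n2_pair()
  fs <- fx$fs
  eeg <- fx$background$samples[1:(fs * 600)]   # 10 min of N2 background
  wf <- somnphen:::spindle_waveform(fs, 13, 30, 1.0)
  t0 <- 300
  idx <- (t0 * fs + 1):(t0 * fs + length(wf))
  eeg[idx] <- eeg[idx] + wf
  ev <- detect_spindles(eeg, fs, cbind(0, 600))
  hits <- which(ev$start < t0 + 1 & ev$end > t0)
  expect_identical(length(hits), 1L)
  expect_gt(interval_iou(ev$start[hits], ev$end[hits], t0, t0 + 1), 0.5)
  expect_lt(abs(ev$frequency[hits] - 13), 0.5)
  expect_gt(ev$amplitude[hits], 15)
  expect_true(ev$start[hits] < ev$peak[hits] &&
                ev$peak[hits] < ev$end[hits])

  # a 0.3-s burst falls below the minimum duration: nothing overlaps it
  eeg2 <- fx$background$samples[1:(fs * 600)]
  wf2 <- somnphen:::spindle_waveform(fs, 13, 30, 0.3)
  eeg2[(t0 * fs + 1):(t0 * fs + length(wf2))] <-
    eeg2[(t0 * fs + 1):(t0 * fs + length(wf2))] + wf2
  ev2 <- detect_spindles(eeg2, fs, cbind(0, 600))
  expect_false(any(ev2$start < t0 + 0.3 & ev2$end > t0))
})

test_that("detector keeps false positives below 0.5 events/min", {
  fx <- fx_n2_pair()
  fp <- detect_spindles(fx$background$samples, fx$fs, fx$n2)
  expect_lt(nrow(fp) / 120, 0.5)
})

test_that("insufficient N2 yields no events", {
  fx <- fx_n2_pair()
  expect_identical(
    nrow(detect_spindles(fx$spindled$samples, fx$fs, cbind(0, 120))), 0L)
  expect_identical(
    nrow(detect_spindles(fx$spindled$samples, fx$fs,
                         matrix(numeric(0), 0, 2))), 0L)
})

test_that("slow-oscillation detector honors its amplitude criteria", {
  fs <- 128
  spec <- group_spec("so", spindle_density = 0, so_rate = 5)
  h3 <- hypnogram(rep("N3", 120))
  e3 <- generate_eeg(h3, spec, fs = fs, seed = 31)
  sos <- detect_slow_oscillations(e3$samples, fs, cbind(0, 120 * 30))
  tr <- e3$truth$sos
  expect_gt(event_recall(tr, sos), 0.95)
  expect_gt(event_precision(tr, sos), 0.95)
  expect_true(all(sos$amplitude >= 75))

  # flat signal: no events
  expect_identical(nrow(detect_slow_oscillations(numeric(fs * 120), fs)), 0L)

  # a 30 uV cycle fails both amplitude criteria
  quiet <- generate_eeg(hypnogram(rep("N3", 20)),
                        group_spec("q", spindle_density = 0, so_rate = 0),
                        fs = fs, seed = 32)$samples
  wf <- somnphen:::so_waveform(fs, 0.8, 30)
  quiet[1000 + seq_along(wf)] <- quiet[1000 + seq_along(wf)] + wf
  sos2 <- detect_slow_oscillations(quiet, fs, cbind(0, 20 * 30))
  t_inj <- 1000 / fs
  expect_false(any(sos2$start < t_inj + 1.25 & sos2$end > t_inj))
})

test_that("spindle summary computes the 10 features with stated bounds", {
  fx <- fx_n2_pair()
  sp <- detect_spindles(fx$spindled$samples, fx$fs, fx$n2)
  sos <- detect_slow_oscillations(fx$spindled$samples, fx$fs, fx$n2)
  sm <- spindle_summary(sp, sos, fx$spindled$samples, fx$fs, fx$n2)
  expect_identical(length(sm), 10L)
  expect_equal(unname(sm["spindle.density"]), nrow(sp) / 120)
  expect_gte(sm["spindle.so_coupling_prop"], 0)
  expect_lte(sm["spindle.so_coupling_prop"], 1)
  expect_gte(sm["spindle.dispersion"], 0)
  expect_lt(abs(sm["spindle.frequency"] - 13), 0.5)
  expect_gt(sm["spindle.sigma_isolation"], 1)

  # invariance to N2 interval ordering
  split_n2 <- rbind(c(0, 1800), c(1800, 7200))
  sm1 <- spindle_summary(sp, sos, fx$spindled$samples, fx$fs, split_n2)
  sm2 <- spindle_summary(sp, sos, fx$spindled$samples, fx$fs,
                         split_n2[2:1, ])
  expect_equal(sm1, sm2)

  # zero spindles: count 0, density 0, averages missing
  none <- sp[0, ]
  sm0 <- spindle_summary(none, sos, fx$spindled$samples, fx$fs, fx$n2)
  expect_identical(unname(sm0["spindle.count"]), 0)
  expect_identical(unname(sm0["spindle.density"]), 0)
  expect_true(is.na(sm0["spindle.frequency"]))

  # density arithmetic: 30 events over 60 minutes
  fake <- data.frame(start = seq(10, 3480, length.out = 30))
  fake$end <- fake$start + 1
  fake$peak <- fake$start + 0.5
  fake$duration <- 1
  fake$amplitude <- 30
  fake$frequency <- 13
  fake$sigma_isolation <- 2
  smd <- spindle_summary(fake, sos[0, ], numeric(128 * 3600), 128,
                         cbind(0, 3600))
  expect_equal(unname(smd["spindle.density"]), 0.5)
})

test_that("coupling statistics follow circular-mean identities", {
  cs <- coupling_stats(rep(pi / 2, 5))
  expect_equal(cs$plv, 1)
  expect_equal(cs$angle, pi / 2)
  # four phases at right angles cancel: zero resultant
  cs0 <- coupling_stats(c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(cs0$plv, 0, tolerance = 1e-12)
  # plv always in [0, 1]
  set.seed(4)
  for (i in 1:20) {
    v <- coupling_stats(runif(10, -pi, pi))$plv
    expect_gte(v, 0); expect_lte(v, 1)
  }
})
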