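# Generator: Markov hypnograms, event-injected EEG, Dirichlet hypnodensity,
# cohort assembly.

test_that("hypnogram generation follows the transition kernel", {
  # absorbing chain: identity kernel starting in N2 stays in N2
  ident <- diag(5)
  dimnames(ident) <- list(stage_levels(), stage_levels())
  spec <- group_spec("abs", transition_matrix = ident,
                     initial_distribution = c(0, 0, 1, 0, 0))
  h <- generate_hypnogram(spec, 50, seed = 1)
  expect_true(all(unclass(h) == "N2"))

  # determinism
  spec2 <- group_spec("d")
  expect_identical(unclass(generate_hypnogram(spec2, 200, seed = 42)),
                   unclass(generate_hypnogram(spec2, 200, seed = 42)))

  # law of large numbers: empirical pairwise transition frequencies on a
  # 50,000-epoch chain recover the kernel within +-0.02, and per-row KL
  # divergence is < 0.01
  h <- generate_hypnogram(spec2, 50000L, seed = 3)
  s <- unclass(h)
  emp <- table(factor(s[-length(s)], stage_levels()),
               factor(s[-1], stage_levels()))
  emp <- emp / rowSums(emp)
  P <- spec2$transition_matrix
  expect_lt(max(abs(emp - P)), 0.02)
  kl <- vapply(1:5, function(i) {
    sel <- P[i, ] > 0
    sum(P[i, sel] * log(P[i, sel] / pmax(emp[i, sel], 1e-12)))
  }, numeric(1))
  expect_lt(max(kl), 0.01)
})

test_that("generator rejects invalid parameters", {
  bad <- default_transition_matrix()
  bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(group_spec("x", transition_matrix = bad), "sum to 1")
  expect_error(group_spec("x", missing_rate = 0.05), "missing_rate")
  expect_error(group_spec("x", hypnodensity_concentration = 0), "positive")
  expect_error(generate_hypnogram(group_spec("x"), 10, seed = 1), ">= 40")
  expect_error(generate_cohort(list(), seed = 1), "at least one")
})

test_that("EEG synthesis injects the stated events and spectra", {
  fx <- fx_n2_pair()
  # density 0 -> empty truth
  expect_identical(nrow(fx$background$truth$spindles), 0L)
  # injected count ~ Poisson(density x minutes of N2)
  lam <- 2 * 120
  n_inj <- nrow(fx$spindled$truth$spindles)
  expect_gt(n_inj, lam - 4 * sqrt(lam))
  expect_lt(n_inj, lam + 4 * sqrt(lam))
  # events lie inside the recording
  expect_true(all(fx$spindled$truth$spindles$start >= 0))
  expect_true(all(fx$spindled$truth$spindles$end <= 240 * 30))

  # delta is the maximal-share band of concatenated N3 epochs (FFT oracle)
  spec <- group_spec("n3", so_rate = 0)
  h3 <- hypnogram(rep("N3", 60))
  e3 <- generate_eeg(h3, spec, fs = 128, seed = 5)
  x <- e3$samples - mean(e3$samples)
  p <- Mod(stats::fft(x))^2
  freqs <- (seq_along(x) - 1) * 128 / length(x)
  bands <- eeg_bands()
  shares <- vapply(seq_len(nrow(bands)), function(b) {
    sum(p[freqs >= bands$low[b] & freqs < bands$high[b]])
  }, numeric(1))
  expect_identical(which.max(shares), 1L)
  expect_gt(shares[1] / sum(shares), 0.5)

  # sigma RMS inside truth spindle intervals exceeds local background RMS
  tr <- fx$spindled$truth$spindles
  sig <- somnphen:::fft_bandpass(fx$spindled$samples, 128, 11, 16)
  in_rms <- sapply(seq_len(min(50, nrow(tr))), function(i) {
    idx <- (floor(tr$start[i] * 128) + 1):ceiling(tr$end[i] * 128)
    sqrt(mean(sig[idx]^2))
  })
  bg_rms <- sqrt(mean(somnphen:::fft_bandpass(
    fx$background$samples, 128, 11, 16)^2))
  expect_true(all(in_rms > bg_rms))

  expect_error(generate_eeg(fx$hyp, group_spec("x"), fs = 50, seed = 1),
               "fs")
})

test_that("hypnodensity rows are Dirichlet draws centered on the stage", {
  spec <- group_spec("h")
  h <- generate_hypnogram(spec, 10000L, seed = 6)
  hd <- generate_hypnodensity(h, 50, seed = 7)
  expect_true(all(abs(rowSums(hd) - 1) < 1e-9))
  expect_true(all(hd >= 0))
  # concentration 50: argmax matches the true stage > 95% of epochs
  hit <- stage_levels()[max.col(hd)] == unclass(h)
  expect_gt(mean(hit), 0.95)
  # near-degenerate concentration: rows approach one-hot
  hd6 <- generate_hypnodensity(hypnogram(rep("N2", 500)), 1e6, seed = 8)
  ent <- apply(hd6, 1, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
  expect_lt(mean(ent), 0.01)
  expect_error(generate_hypnodensity(h, 0, seed = 1), "positive")
})

test_that("cohort assembly is deterministic with per-participant seeds", {
  specs <- list(group_spec("A", n_participants = 3,
                           n_epochs_range = c(60L, 80L)),
                group_spec("B", n_participants = 4,
                           n_epochs_range = c(60L, 80L)))
  co <- generate_cohort(specs, seed = 5)
  expect_identical(nrow(co$cohort), 7L)
  expect_identical(co$cohort$group, c(rep("A", 3), rep("B", 4)))
  co2 <- generate_cohort(specs, seed = 5)
  expect_identical(co$participants[[5]]$eeg, co2$participants[[5]]$eeg)
  expect_identical(unclass(co$participants[[2]]$hypnogram),
                   unclass(co2$participants[[2]]$hypnogram))
})

test_that("feature-cell missingness lands at the specified rate", {
  specs <- list(group_spec("A", n_participants = 6, missing_rate = 0.02,
                           n_epochs_range = c(120L, 140L)),
                group_spec("B", n_participants = 6, missing_rate = 0.02,
                           n_epochs_range = c(120L, 140L)))
  co <- generate_cohort(specs, seed = 9)
  tab <- extract_cohort_features(co)
  feat <- as.matrix(tab[, feature_catalog()$name])
  # compare against the same extraction without injection: only injected
  # cells count toward the rate (structurally-missing cells are shared)
  tab0 <- extract_cohort_features(co, inject_missing = FALSE)
  feat0 <- as.matrix(tab0[, feature_catalog()$name])
  injected <- is.na(feat) & !is.na(feat0)
  denom <- sum(!is.na(feat0))
  expect_lt(abs(sum(injected) / denom - 0.02), 0.005)
})
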