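test_that("canonical HRF peaks at the configured delay on a dense grid", {
  fs <- 100  # dense grid oracle
  k <- canonical_hrf(hrf_params(), fs)
  expect_lt(abs((which.max(k) - 1) / fs - 6), 1 / fs + 1e-9)
  # doubling the sampling rate leaves the peak time unchanged
  k2 <- canonical_hrf(hrf_params(), 2 * fs)
  expect_lt(abs((which.max(k2) - 1) / (2 * fs) - 6), 1 / fs)
  # no undershoot -> single gamma, non-negative everywhere
  k0 <- canonical_hrf(hrf_params(undershoot_ratio = 0), 10.2)
  expect_true(all(k0 >= 0))
  expect_error(canonical_hrf(hrf_params(peak_dispersion = -1)), "positive")
})

test_that("neural design is non-zero exactly on the active-training span", {
  tl <- build_session_timeline(protocol_config(), 1)
  fs <- 10.2
  d <- neural_design(tl, c(induction = 1, regulation = 0.5), fs)
  t <- (seq_along(d) - 1) / fs
  expect_true(all(d[t < 240] == 0))
  expect_true(all(d[t >= 240 & t < 1140] > 0))
  # 5 blocks x 30 s of induction at gain 1
  expect_equal(sum(d == 1) / fs, 150, tolerance = 1e-6)
  expect_true(all(neural_design(tl, c(induction = 0, regulation = 0), fs) == 0))
})

test_that("concentration simulation matches a brute-force convolution", {
  fs <- 10.2
  k <- canonical_hrf(hrf_params(), fs)
  k <- k / sum(k)
  toy <- c(rep(1, 10), rep(0, 10))
  m <- montage2()
  conc <- simulate_concentrations(
    cbind(induction = toy, regulation = numeric(20)),
    learning = learning_profile(list(`S3-D2` = 1, `S5-D5` = 1)),
    montage = m, sampling_rate = fs, amplitude = 1)
  brute <- vapply(seq_len(20), function(t)
    sum(toy[seq_len(t)] * k[t - seq_len(t) + 1]), 1)
  expect_equal(unname(conc$hbo["S3-D2", ]), brute, tolerance = 1e-12)
  # linearity in the learning multiplier of the regulation drive
  d <- cbind(induction = numeric(20), regulation = toy)
  c1 <- simulate_concentrations(d, learning = learning_profile(list(`S5-D5` = 1)),
                                montage = m, sampling_rate = fs)
  c2 <- simulate_concentrations(d, learning = learning_profile(list(`S5-D5` = 2)),
                                montage = m, sampling_rate = fs)
  expect_equal(c2$hbo["S5-D5", ], 2 * c1$hbo["S5-D5", ], tolerance = 1e-12)
  # HbR is the fixed negative multiple of HbO
  expect_equal(c1$hbr, -c1$hbo / 3, tolerance = 1e-12)
  # zero design -> zero concentrations
  c0 <- simulate_concentrations(cbind(induction = numeric(20),
                                      regulation = numeric(20)),
                                learning = learning_profile(list(`S5-D5` = 1)),
                                montage = m, sampling_rate = fs)
  expect_true(all(c0$hbo == 0))
  expect_error(simulate_concentrations(d,
    learning = learning_profile(list(`S9-D9` = 2)), montage = m),
    "absent from the montage")
})

test_that("forward MBLL is an exact linear map", {
  m <- montage2()
  set.seed(4)
  conc <- list(hbo = matrix(rnorm(40) * 1e-6, 2, 20,
                            dimnames = list(m$channels$label, NULL)))
  conc$hbr <- -conc$hbo / 3
  od <- forward_mbll(conc, mbll_params(), m)
  od2 <- forward_mbll(list(hbo = 2 * conc$hbo, hbr = 2 * conc$hbr),
                      mbll_params(), m)
  expect_equal(od2$od760, 2 * od$od760, tolerance = 1e-12)
  zero <- forward_mbll(list(hbo = 0 * conc$hbo, hbr = 0 * conc$hbr),
                       mbll_params(), m)
  expect_true(all(zero$od850 == 0))
  sing <- mbll_params()
  sing$extinction[2, ] <- sing$extinction[1, ]
  expect_error(forward_mbll(conc, sing, m), "singular")
})

test_that("intensity synthesis is positive, deterministic and spectrally faithful", {
  tl <- build_session_timeline(protocol_config(), 1)
  rec <- clean_session()
  expect_true(all(rec$intensity[[1]] > 0))
  expect_true(all(rec$intensity[[2]] > 0))
  # no noise, zero OD -> constant baseline intensity
  odz <- list(od760 = matrix(0, 1, 100, dimnames = list("S3-D2", NULL)),
              od850 = matrix(0, 1, 100, dimnames = list("S3-D2", NULL)))
  const <- synthesize_intensity(odz, silent_noise(), baseline_intensity = 500)
  expect_true(all(const[[1]] == 500))
  # determinism under a fixed seed
  nz <- noise_params(rng_seed = 99)
  i1 <- synthesize_intensity(odz, nz)
  i2 <- synthesize_intensity(odz, nz)
  expect_identical(i1, i2)
  # cardiac line shows up at the configured frequency in the periodogram
  fs <- 10.2
  nzc <- noise_params(cardiac_amp = 0.01, resp_amp = 0, mayer_amp = 0,
                      drift_slope = 0, white_sd = 1e-5,
                      motion_spike_amp = 0, rng_seed = 5)
  odl <- list(od760 = matrix(0, 1, 4096, dimnames = list("S3-D2", NULL)),
              od850 = matrix(0, 1, 4096, dimnames = list("S3-D2", NULL)))
  ii <- synthesize_intensity(odl, nzc, sampling_rate = fs)
  sp <- stats::spec.pgram(log10(ii[[1]][1, ]), plot = FALSE, taper = 0)
  fpeak <- sp$freq[which.max(sp$spec)] * fs
  expect_lt(abs(fpeak - 1.1), fs / 4096 + 1e-6)  # within one frequency bin
})

test_that("programme simulation is reproducible with per-session ground truth", {
  cfg <- protocol_config()
  p1 <- simulate_programme(cfg, n_sessions = 2, seed = 8, montage = montage2())
  p2 <- simulate_programme(cfg, n_sessions = 2, seed = 8, montage = montage2())
  expect_identical(p1[[1]]$intensity, p2[[1]]$intensity)
  expect_identical(p1[[2]]$intensity, p2[[2]]$intensity)
  expect_length(p1, 2)
  expect_equal(ncol(p1[[1]]$intensity[[1]]), round(1140 * 10.2))
  # learning profile: control-segment ground-truth amplitude rises 1 -> 2
  tl <- p1[[1]]$timeline
  fs <- p1[[1]]$sampling_rate
  reg_idx <- which(neural_design(tl, c(induction = 0, regulation = 1), fs) > 0)
  a1 <- mean(p1[[1]]$ground_truth$hbo["S5-D5", reg_idx])
  a2 <- mean(p1[[2]]$ground_truth$hbo["S5-D5", reg_idx])
  expect_gt(a2, a1)
  expect_error(simulate_programme(cfg, n_sessions = 9), "exceeds")
})
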