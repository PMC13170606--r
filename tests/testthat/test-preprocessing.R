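test_that("FIR design yields symmetric taps with deep stopband attenuation", {
  taps <- design_fir(filter_spec(), 10.2)
  expect_length(taps, 1001)
  expect_lt(max(abs(taps - rev(taps))), 1e-12)   # linear phase
  gain <- function(f) Mod(sum(taps * exp(-2i * pi * f / 10.2 * (0:1000))))
  expect_gt(20 * log10(gain(0.05) / gain(1.0)), 40)
  expect_error(design_fir(filter_spec(band = c(0.01, 6)), 10.2), "Nyquist")
  expect_error(filter_spec(band = c(0.05, 0.05)), "low < high")
})

test_that("zero-phase application leaves passband phase untouched", {
  fs <- 10.2
  taps <- design_fir(filter_spec(), fs)
  t <- (0:11627) / fs
  s <- sin(2 * pi * 0.05 * t)
  y <- apply_zero_phase(s, taps)
  cc <- stats::ccf(y, s, lag.max = 3, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)     # no group delay
  expect_equal(sd(y) / sd(s), 1, tolerance = 0.01)
  expect_true(all(apply_zero_phase(numeric(500), taps) == 0))
  # time-reversal symmetry of a zero-phase system
  set.seed(6); x <- rnorm(3000)
  expect_equal(apply_zero_phase(rev(x), taps),
               rev(apply_zero_phase(x, taps)), tolerance = 1e-9)
})

test_that("optical-density conversion is exact and scale-invariant", {
  expect_equal(as.numeric(to_optical_density(numeric(10), 100)), numeric(10))
  # single sample with filtered = 9 x mean: -log10(10) = -1
  expect_equal(as.numeric(to_optical_density(900, 100)), -1)
  set.seed(7); f <- rnorm(100)
  od1 <- to_optical_density(f, 50)
  od10 <- to_optical_density(10 * f, 500)
  expect_equal(as.numeric(od1), as.numeric(od10), tolerance = 1e-12)
  # clipping is counted, not silent
  odc <- to_optical_density(c(-200, 1), 100)
  expect_equal(attr(odc, "n_clipped"), 1)
  expect_error(to_optical_density(1:3, -1), "positive")
})

test_that("MBLL inversion is the exact inverse of the forward model", {
  m <- montage2()
  set.seed(8)
  conc <- list(hbo = matrix(rnorm(100) * 1e-6, 2, 50,
                            dimnames = list(m$channels$label, NULL)))
  conc$hbr <- matrix(rnorm(100) * 3e-7, 2, 50,
                     dimnames = list(m$channels$label, NULL))
  od <- forward_mbll(conc, mbll_params(), m)
  for (i in 1:2) {
    sep <- m$channels$separation_mm[i] / 10
    inv <- mbll_invert(od$od760[i, ], od$od850[i, ], separation_cm = sep)
    expect_lt(max(abs(inv$hbo - conc$hbo[i, ])) / max(abs(conc$hbo[i, ])),
              1e-10)
    expect_lt(max(abs(inv$hbr - conc$hbr[i, ])) / max(abs(conc$hbr[i, ])),
              1e-10)
  }
  # zero OD -> zero concentrations; separation scaling is 1/L
  z <- mbll_invert(numeric(5), numeric(5))
  expect_true(all(z$hbo == 0) && all(z$hbr == 0))
  i1 <- mbll_invert(od$od760[1, ], od$od850[1, ], separation_cm = 3)
  i2 <- mbll_invert(od$od760[1, ], od$od850[1, ], separation_cm = 6)
  expect_equal(i1$hbo, 2 * i2$hbo, tolerance = 1e-12)
  expect_error(mbll_invert(1:3, 1:4), "equal length")
})

test_that("demean + RMS normalisation honours its contract", {
  y <- demean_rms_normalize(c(1, 2, 3))
  expect_lt(abs(mean(y)), 1e-9)
  expect_lt(abs(sqrt(mean(y^2)) - 1), 1e-9)
  set.seed(9); x <- rnorm(200, 5, 2)
  expect_equal(demean_rms_normalize(3 * x + 10), demean_rms_normalize(x),
               tolerance = 1e-12)                    # affine invariance
  expect_equal(demean_rms_normalize(-x), -demean_rms_normalize(x),
               tolerance = 1e-12)                    # sign equivariance
  expect_error(demean_rms_normalize(rep(2, 10)), "degenerate")
})

test_that("cropping trims padding and preserves the protocol span", {
  tl <- build_session_timeline(protocol_config(), 1)
  rec <- simulate_session(tl, 1, montage = montage2(),
                          noise = silent_noise(), pad_s = 10)
  cropped <- crop_to_protocol(rec)
  expect_equal(ncol(cropped$intensity[[1]]), round(1140 * 10.2))
  expect_equal(min(cropped$timeline$onset), 0)
  # a recording exactly spanning the protocol is unchanged
  exact <- clean_session()
  expect_identical(crop_to_protocol(exact)$intensity, exact$intensity)
  short <- exact
  short$intensity <- lapply(short$intensity, function(m) m[, 1:100])
  expect_error(crop_to_protocol(short), "exceeds")
})

test_that("pipeline output is normalised and recovers band-limited truth", {
  rec <- clean_session()
  h <- preprocess_pipeline(rec)
  expect_lt(max(abs(rowMeans(h$hbo))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(h$hbo^2)) - 1)), 1e-9)
  expect_equal(h$provenance$stages,
               c("crop", "fir_bandpass", "wavelet_denoise",
                 "optical_density", "mbll_invert", "demean_rms"))
  # against the ground truth passed through the same band limitation
  taps <- design_fir(filter_spec(), rec$sampling_rate)
  for (ch in h$channels) {
    truth <- rec$ground_truth$hbo[ch, ]
    btruth <- wavelet_denoise(apply_zero_phase(truth - mean(truth), taps))
    expect_gt(stats::cor(h$hbo[ch, ], btruth), 0.999)
    expect_gt(stats::cor(h$hbo[ch, ], truth), 0.9)
  }
})

test_that("a single transient response is recovered faithfully", {
  cfg1 <- protocol_config(n_blocks = 1)
  tl1 <- build_session_timeline(cfg1, 1)
  rec1 <- simulate_session(tl1, 1, montage = montage2(),
                           noise = silent_noise(),
                           gains = c(induction = 1, regulation = 0))
  h1 <- preprocess_pipeline(rec1)
  expect_gt(stats::cor(h1$hbo["S5-D5", ], rec1$ground_truth$hbo["S5-D5", ]),
            0.9)
})

test_that("pipeline is invariant to raw-intensity rescaling", {
  rec <- clean_session()
  h <- preprocess_pipeline(rec)
  for (c_scale in c(0.1, 3, 10)) {
    rs <- rec
    rs$intensity <- lapply(rs$intensity, function(m) c_scale * m)
    hs <- preprocess_pipeline(rs)
    expect_lt(max(abs(hs$hbo - h$hbo)), 1e-8)
    expect_lt(max(abs(hs$hbr - h$hbr)), 1e-8)
  }
})

test_that("duplicated channels preprocess identically", {
  rec <- clean_session()
  rec$intensity <- lapply(rec$intensity, function(m) {
    m["S3-D2", ] <- m["S5-D5", ]; m
  })
  # give the duplicate the same separation so the chains match exactly
  rec$montage$channels$separation_mm <- c(35, 35)
  h <- preprocess_pipeline(rec)
  expect_equal(h$hbo["S3-D2", ], h$hbo["S5-D5", ], tolerance = 1e-12)
})

test_that("white-noise input leaves the pipeline almost entirely below 0.2 Hz", {
  fs <- 10.2
  rec <- clean_session()
  set.seed(10)
  rec$intensity <- lapply(rec$intensity, function(m) {
    for (i in seq_len(nrow(m))) m[i, ] <- 1000 + rnorm(ncol(m), 0, 10)
    m
  })
  h <- preprocess_pipeline(rec)
  for (ch in h$channels) {
    x <- h$hbo[ch, ]
    P <- Mod(stats::fft(x))^2
    fr <- (seq_along(x) - 1) / length(x) * fs
    low <- fr < 0.2 | fr > fs - 0.2
    expect_gt(sum(P[low]) / sum(P), 0.95)
  }
})
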