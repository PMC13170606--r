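test_that("epoching produces scheduler-predicted counts and exact lengths", {
  rec <- clean_session()
  h <- preprocess_pipeline(rec)
  ep <- extract_epochs(h)
  # 5 stressor + 25 control events x 2 channels x 2 chromophores
  expect_length(ep$epochs, 30 * 2 * 2)
  expect_equal(ep$n_discarded, 0)
  lens <- vapply(ep$epochs, function(e) length(e$samples), 1L)
  expect_true(all(lens == round(15 * 10.2)))  # 153 samples
  expect_equal(sum(vapply(ep$epochs, function(e)
    e$condition == "stressor", TRUE)), 5 * 4)
  # an epoch longer than the tail of the last block is discarded, counted
  ep2 <- extract_epochs(h, epoch_duration = 40)
  expect_gt(ep2$n_discarded, 0)
  empty <- h; empty$timeline <- h$timeline[0, ]
  expect_error(extract_epochs(empty), "empty")
})

test_that("epoch energy equals a brute-force sum of squares", {
  expect_equal(epoch_energy(c(1, 1, 1, 1)), 4)
  expect_equal(epoch_energy(c(3, -4)), 25)
  brute <- function(v) {
    sq <- numeric(length(v))
    for (j in seq_along(v)) sq[j] <- v[j] * v[j]
    sum(sq)
  }
  set.seed(12)
  for (i in 1:20) {
    v <- rnorm(153)
    expect_identical(epoch_energy(v), brute(v))
  }
  expect_error(epoch_energy(numeric(0)), "empty")
})

test_that("energy ratios normalise to unit group mean", {
  mk <- function(energy_sqrt, cond, i) list(channel = "S1-D1",
    chromophore = "hbo", condition = cond, onset = i * 30,
    session = 1L, samples = c(energy_sqrt))
  # two epochs with energies 2 and 4 -> ratios 2/3 and 4/3
  eps <- list(mk(sqrt(2), "control", 1), mk(sqrt(4), "control", 2))
  er <- energy_ratios(eps)
  expect_equal(sort(er$ratio), c(2 / 3, 4 / 3), tolerance = 1e-12)
  # identical epochs -> all ratios exactly 1
  same <- lapply(1:6, function(i) mk(1.3, "control", i))
  expect_true(all(energy_ratios(same)$ratio == 1))
  # stationary white noise, 30 epochs: mean ratio 1 to machine precision
  set.seed(13)
  wn <- lapply(1:30, function(i) list(channel = "S1-D1",
    chromophore = "hbo", condition = if (i <= 5) "stressor" else "control",
    onset = i * 30, session = 1L, samples = rnorm(153)))
  er2 <- energy_ratios(wn)
  expect_lt(abs(mean(er2$ratio) - 1), 1e-12)
  expect_gt(sd(er2$ratio), 0)
  zero <- lapply(1:3, function(i) mk(0, "control", i))
  expect_error(energy_ratios(zero), "degenerate")
})

test_that("per-event averages respect ratio normalisation", {
  rec <- clean_session()
  h <- preprocess_pipeline(rec)
  er <- energy_ratios(extract_epochs(h)$epochs)
  ev <- average_by_event(er)
  # pooled mean over conditions, weighted by epoch counts, is exactly 1
  for (ch in unique(ev$channel)) for (cr in c("hbo", "hbr")) {
    g <- ev[ev$channel == ch & ev$chromophore == cr, ]
    expect_lt(abs(sum(g$mean_ratio * g$n_epochs) / sum(g$n_epochs) - 1),
              1e-9)
  }
  # permutation invariance
  ev2 <- average_by_event(er[sample(nrow(er)), ])
  expect_equal(ev2, ev)
})

test_that("session summaries produce ordered boxplot statistics", {
  rec <- clean_session()
  h <- preprocess_pipeline(rec)
  er <- energy_ratios(extract_epochs(h)$epochs)
  sm <- summarize_sessions(er)
  expect_true(all(sm$q1 <= sm$median & sm$median <= sm$q3))
  expect_true(all(sm$whisker_low <= sm$q1 & sm$q3 <= sm$whisker_high))
  expect_error(summarize_sessions(er, channels = "S9-D9"), "available")
  # constant ratios give zero interquartile range
  const <- data.frame(channel = "A", chromophore = "hbo", session = 1,
                      condition = "control", ratio = rep(1, 8))
  smc <- summarize_sessions(const)
  expect_equal(smc$q3 - smc$q1, 0)
})

test_that("trend classification follows the declared plateau rule", {
  expect_equal(classify_trend(c(1.0, 1.3, 1.6, 1.61)), "rising_then_plateau")
  expect_equal(classify_trend(c(1.0, 1.2, 1.4, 1.7)), "rising_throughout")
  expect_equal(classify_trend(c(1.0, 1.0, 1.0, 1.0)), "flat")
  expect_equal(classify_trend(c(1.0, 1.5, 1.2, 1.3)), "other")
  expect_error(classify_trend(c(1, 2)), "at least 3")
})

test_that("raising the control drive shifts ratio mass toward control", {
  tl <- build_session_timeline(protocol_config(), 1)
  m <- montage2()
  mean_by_cond <- function(mult) {
    rec <- simulate_session(tl, 1, montage = m, noise = silent_noise(),
                            learning = learning_profile(
                              list(`S3-D2` = mult, `S5-D5` = mult)))
    h <- preprocess_pipeline(rec)
    ev <- average_by_event(energy_ratios(extract_epochs(h)$epochs))
    g <- ev[ev$channel == "S5-D5" & ev$chromophore == "hbo", ]
    stats::setNames(g$mean_ratio, g$condition)
  }
  lo <- mean_by_cond(1)
  hi <- mean_by_cond(2.5)
  expect_gt(hi[["control"]], lo[["control"]])
  expect_lt(hi[["stressor"]], lo[["stressor"]])
})

test_that("the programme analysis object prints, summarises and classifies", {
  recs <- simulate_programme(n_sessions = 3, seed = 21, montage = montage2(),
                             noise = silent_noise())
  ana <- analyze_programme(recs)
  expect_s3_class(ana, "nf_energy")
  expect_true(all(c("S3-D2", "S5-D5") %in% names(ana$trends)))
  expect_output(print(ana), "Energy-ratio analysis")
  expect_true(all(c("q1", "median", "q3") %in% names(summary(ana))))
  tmp <- tempfile(fileext = ".pdf")
  grDevices::pdf(tmp); plot(ana); grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
})
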