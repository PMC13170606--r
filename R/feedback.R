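#' Online feedback configuration
#'
#' Parameters of the real-time thermometer feedback loop: a causal online
#' bandpass isolating the hemodynamic range (0.01-0.3 Hz by default,
#' matching the online processing band of commercial neurofeedback
#' software), the ROI channel driving the display, the baseline window used
#' to reference the signal, the display update interval, and a linear
#' mapping from baseline z-units to quantized thermometer levels.
#'
#' @param online_band `c(low, high)` Hz.
#' @param roi_channels channel label(s) averaged into the ROI signal.
#' @param baseline_window seconds of baseline used for reference statistics.
#' @param update_interval seconds between display updates.
#' @param thermometer_levels number of quantized display levels (>= 2).
#' @param z_span z-score range mapped onto the full thermometer.
#' @return Object of class `feedback_config`.
#' @export
feedback_config <- function(online_band = c(0.01, 0.3),
                            roi_channels = "S5-D5",
                            baseline_window = 180,
                            update_interval = 1,
                            thermometer_levels = 10,
                            z_span = c(-2, 2)) {
  if (online_band[1] <= 0 || online_band[2] <= online_band[1])
    stop("online_band must satisfy 0 < low < high")
  if (thermometer_levels < 2) stop("need at least 2 thermometer levels")
  structure(list(online_band = online_band, roi_channels = roi_channels,
                 baseline_window = baseline_window,
                 update_interval = update_interval,
                 thermometer_levels = as.integer(thermometer_levels),
                 z_span = z_span),
            class = "feedback_config")
}

# Causal second-order-section Butterworth bandpass coefficients.
online_filter_coefs <- function(config, sampling_rate) {
  nyq <- sampling_rate / 2
  if (config$online_band[2] >= nyq)
    stop("online band upper edge must lie below Nyquist")
  bt <- signal::butter(2, config$online_band / nyq, type = "pass")
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

# Direct-form-II-transposed IIR step with explicit state, so streaming
# chunks produce bit-identical output to one-shot filtering (causality).
iir_filter_state <- function(b, a, x, zi = NULL) {
  nb <- length(b); na <- length(a)
  nz <- max(nb, na) - 1L
  if (is.null(zi)) zi <- numeric(nz)
  b <- c(b, numeric(nz + 1L - nb)); a <- c(a, numeric(nz + 1L - na))
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + zi[1]
    if (nz > 1)
      for (k in seq_len(nz - 1L))
        zi[k] <- b[k + 1] * x[i] + zi[k + 1] - a[k + 1] * y[i]
    zi[nz] <- b[nz + 1] * x[i] - a[nz + 1] * y[i]
  }
  list(y = y, zi = zi)
}

#' Causal online bandpass filter
#'
#' Second-order Butterworth bandpass applied causally (forward only), as a
#' real-time system must: the output at time t depends only on samples up
#' to t. Zero-phase filtering is impossible online; the offline analysis
#' path is unaffected.
#'
#' @param x numeric signal (a stream).
#' @param config a [feedback_config()].
#' @param sampling_rate Hz.
#' @return Filtered signal of the same length.
#' @export
online_filter <- function(x, config = feedback_config(),
                          sampling_rate = 10.2) {
  co <- online_filter_coefs(config, sampling_rate)
  iir_filter_state(co$b, co$a, x)$y
}

#' Map a baseline-referenced ROI value to a thermometer level
#'
#' Linear in baseline z-units over `z_span`, quantized to
#' `thermometer_levels` integer levels in `[0, levels - 1]` and clipped at
#' the range ends. The baseline mean maps to the middle level; the mapping
#' is monotone non-decreasing.
#'
#' @param roi_value filtered ROI signal value.
#' @param baseline_stats list with `mean` and `sd` from the baseline window.
#' @param config a [feedback_config()].
#' @return Integer level.
#' @export
thermometer_level <- function(roi_value, baseline_stats,
                              config = feedback_config()) {
  if (is.null(baseline_stats$mean) || is.null(baseline_stats$sd) ||
      !is.finite(baseline_stats$sd) || baseline_stats$sd <= 0)
    stop("baseline statistics missing; collect the baseline window first")
  z <- (roi_value - baseline_stats$mean) / baseline_stats$sd
  lv <- config$thermometer_levels
  span <- config$z_span
  lev <- floor((z - span[1]) / (span[2] - span[1]) * lv) +
    (lv %/% 2L - floor((0 - span[1]) / (span[2] - span[1]) * lv))
  as.integer(pmin(lv - 1L, pmax(0L, lev)))
}

#' Constant-gain (null) responder
#'
#' Ignores the displayed level; the closed loop degenerates to an open-loop
#' run with fixed regulation gain.
#'
#' @param gain fixed regulation gain.
#' @return A responder function `(level, state) -> list(gain, state)`.
#' @export
null_responder <- function(gain = 0.6) {
  function(level, state) list(gain = gain, state = state)
}

#' Positive-learning responder
#'
#' Nudges the regulation gain up whenever the displayed level is above the
#' middle of the thermometer and down otherwise, accumulating across
#' updates and sessions — a minimal model of feedback-driven
#' self-regulatory learning.
#'
#' @param start initial regulation gain.
#' @param eta learning rate per update.
#' @param range permissible gain range.
#' @param levels thermometer level count (to locate the midpoint).
#' @return A responder function.
#' @export
learning_responder <- function(start = 0.6, eta = 0.004,
                               range = c(0.1, 2.5), levels = 10) {
  mid <- (levels - 1) / 2
  function(level, state) {
    g <- if (is.null(state$gain)) start else state$gain
    g <- min(range[2], max(range[1], g + eta * (level - mid) / levels))
    list(gain = g, state = list(gain = g))
  }
}

#' Run the closed-loop thermometer feedback simulation
#'
#' Streams one or more sessions sample block by sample block: at each
#' update interval the ROI signal (clean hemodynamic OD plus physiological
#' noise) is causally band-filtered, referenced to the session's baseline
#' statistics, quantized to a thermometer level and shown to the responder,
#' whose returned gain drives the regulation-condition neural design of the
#' next interval. Responder state persists across sessions.
#'
#' @param timelines list of session event timelines.
#' @param responder responder function `(level, state) -> list(gain, state)`.
#' @param config a [feedback_config()].
#' @param hrf an [hrf_params()].
#' @param noise a [noise_params()].
#' @param sampling_rate Hz.
#' @param seed integer seed for the noise stream.
#' @param signal_scale OD amplitude of a unit hemodynamic response.
#' @return List of per-session results, each with `trace` (data frame
#'   `time_s`, `roi_value`, `level`, `gain`), `hbo` (modulated ground-truth
#'   response) and `design`.
#' @export
run_closed_loop <- function(timelines, responder = learning_responder(),
                            config = feedback_config(),
                            hrf = hrf_params(), noise = noise_params(),
                            sampling_rate = 10.2, seed = 1L,
                            signal_scale = 0.02) {
  if (inherits(timelines, "event_timeline")) timelines <- list(timelines)
  co <- online_filter_coefs(config, sampling_rate)
  kern <- canonical_hrf(hrf, sampling_rate)
  kern <- kern / sum(kern)  # unit steady-state gain, as in the simulator
  state <- list()
  out <- vector("list", length(timelines))
  for (s in seq_along(timelines)) {
    tl <- timelines[[s]]
    n <- round(attr(tl, "total_duration") * sampling_rate)
    dsn <- neural_design(tl, c(induction = 1, regulation = 1),
                         sampling_rate, split = TRUE)
    ns <- noise; ns$rng_seed <- derive_seed(seed, "feedback", s)
    nz <- make_od_noise(n, sampling_rate, ns, ns$rng_seed)$w1
    step <- max(1L, round(config$update_interval * sampling_rate))
    nb <- round(config$baseline_window * sampling_rate)
    resp <- numeric(n + length(kern))
    measured <- numeric(n)
    filt_state <- NULL
    gain <- responder(config$thermometer_levels %/% 2L, state)$gain
    trace <- list()
    bstats <- NULL
    design <- numeric(n)
    i <- 1L
    while (i <= n) {
      idx <- i:min(n, i + step - 1L)
      # fix this interval's design with the current regulation gain
      design[idx] <- dsn[idx, "induction"] + gain * dsn[idx, "regulation"]
      for (t in idx) {
        if (design[t] != 0) {
          ki <- t:(t + length(kern) - 1L)
          resp[ki] <- resp[ki] + design[t] * kern
        }
      }
      measured[idx] <- signal_scale * resp[idx] + nz[idx]
      fs_out <- iir_filter_state(co$b, co$a, measured[idx], filt_state)
      filt_state <- fs_out$zi
      roi_now <- mean(fs_out$y)
      last <- idx[length(idx)]
      if (is.null(bstats) && last >= nb) {
        # baseline window complete: freeze reference statistics
        bfil <- online_filter(measured[seq_len(nb)], config, sampling_rate)
        bstats <- list(mean = mean(bfil), sd = stats::sd(bfil))
      }
      level <- if (is.null(bstats)) config$thermometer_levels %/% 2L
        else thermometer_level(roi_now, bstats, config)
      rr <- responder(level, state)
      if (!is.finite(rr$gain) || rr$gain < 0)
        stop("responder returned an out-of-range gain")
      gain <- rr$gain; state <- rr$state
      trace[[length(trace) + 1L]] <- data.frame(
        time_s = (last - 1) / sampling_rate, roi_value = roi_now,
        level = level, gain = gain)
      i <- i + step
    }
    out[[s]] <- list(trace = do.call(rbind, trace),
                     hbo = signal_scale * resp[seq_len(n)],
                     design = design,
                     session_index = attr(tl, "session_index"))
  }
  out
}
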