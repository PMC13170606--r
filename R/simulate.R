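#' Canonical double-gamma hemodynamic response parameters
#'
#' The field-standard canonical HRF: a gamma density peaking ~6 s after
#' stimulus minus a scaled gamma undershoot peaking ~16 s. `hbr_scale` is
#' the fixed negative coupling of deoxy- to oxyhemoglobin responses.
#'
#' @param peak_delay,undershoot_delay gamma peak times (s).
#' @param peak_dispersion,undershoot_dispersion gamma width parameters (s).
#' @param undershoot_ratio relative undershoot amplitude (1/6 is canonical).
#' @param hbr_scale negative HbR/HbO amplitude ratio.
#' @return Object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, hbr_scale = -1 / 3) {
  if (peak_dispersion <= 0 || undershoot_dispersion <= 0)
    stop("dispersions must be positive")
  if (hbr_scale >= 0) stop("hbr_scale must be negative")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio, hbr_scale = hbr_scale),
            class = "hrf_params")
}

#' Evaluate the canonical double-gamma HRF kernel
#'
#' @param params an [hrf_params()].
#' @param sampling_rate Hz.
#' @param duration kernel support in seconds (>= 30 s).
#' @return Numeric kernel sampled at `sampling_rate`, normalised to unit
#'   peak so design gains are in response-amplitude units.
#' @export
canonical_hrf <- function(params = hrf_params(), sampling_rate = 10.2,
                          duration = 32) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  duration <- max(duration, 30)
  t <- seq(0, duration, by = 1 / sampling_rate)
  # mode-parameterised gammas: mode of gamma(shape, scale) is
  # (shape - 1) * scale, so shape = 1 + delay/dispersion peaks at delay
  a1 <- 1 + params$peak_delay / params$peak_dispersion
  a2 <- 1 + params$undershoot_delay / params$undershoot_dispersion
  k <- stats::dgamma(t, shape = a1, scale = params$peak_dispersion) -
    params$undershoot_ratio *
      stats::dgamma(t, shape = a2, scale = params$undershoot_dispersion)
  k / max(k)
}

#' Build the neural design series for a session
#'
#' Piecewise-constant neural drive on the session's sampling grid: induction
#' segments at the induction gain, regulation segments at the regulation
#' gain, baseline and contextualisation at zero.
#'
#' @param timeline an event timeline.
#' @param gains named numeric vector `c(induction =, regulation =)`.
#' @param sampling_rate Hz.
#' @param split if `TRUE`, return a two-column matrix with the induction and
#'   regulation components separately (columns `induction`, `regulation`),
#'   so session-wise learning can rescale the regulation drive alone.
#' @return Numeric vector of length `round(total_duration * sampling_rate)`,
#'   or a matrix when `split = TRUE`.
#' @export
neural_design <- function(timeline, gains = c(induction = 1, regulation = 0.6),
                          sampling_rate = 10.2, split = FALSE) {
  n <- round(attr(timeline, "total_duration") * sampling_rate)
  ind <- numeric(n); reg <- numeric(n)
  blocks <- unique(timeline$block[!is.na(timeline$block)])
  for (b in blocks) {
    bev <- timeline[!is.na(timeline$block) & timeline$block == b, ]
    b0 <- min(bev$onset)
    b1 <- max(bev$onset + bev$duration)
    ion <- bev$onset[bev$event_type == "induction_prompt"]
    idur <- bev$duration[bev$event_type == "induction_prompt"]
    for (k in seq_along(ion)) {
      i <- (round(ion[k] * sampling_rate) + 1):round((ion[k] + idur[k]) * sampling_rate)
      ind[i[i <= n]] <- gains[["induction"]]
    }
    # regulation fills the rest of the block
    bi <- (round(b0 * sampling_rate) + 1):round(b1 * sampling_rate)
    bi <- bi[bi <= n]
    reg[bi[ind[bi] == 0]] <- gains[["regulation"]]
  }
  if (split) cbind(induction = ind, regulation = reg) else ind + reg
}

#' Physiological and instrumental noise parameters
#'
#' Amplitudes are in optical-density units on the log-intensity scale.
#' Defaults place the cardiac, respiratory and Mayer-wave oscillations at
#' 1.1, 0.25 and 0.1 Hz, all below the 5.1 Hz Nyquist frequency of a
#' 10.2 Hz system, with a slow drift, white measurement noise, and
#' Poisson-timed motion spikes with exponential decay.
#'
#' @param cardiac_freq,resp_freq,mayer_freq oscillation frequencies (Hz).
#' @param cardiac_amp,resp_amp,mayer_amp oscillation amplitudes (OD units).
#' @param drift_slope linear drift (OD/s).
#' @param white_sd white-noise standard deviation (OD units).
#' @param motion_spike_rate expected motion artifacts per minute.
#' @param motion_spike_amp spike amplitude (OD units).
#' @param motion_decay_s spike exponential decay constant (s).
#' @param rng_seed integer seed.
#' @return Object of class `noise_params`.
#' @export
noise_params <- function(cardiac_freq = 1.1, resp_freq = 0.25,
                         mayer_freq = 0.1,
                         cardiac_amp = 0.004, resp_amp = 0.006,
                         mayer_amp = 0.008,
                         drift_slope = 2e-5, white_sd = 0.002,
                         motion_spike_rate = 0.5, motion_spike_amp = 0.05,
                         motion_decay_s = 2, rng_seed = 1L) {
  fr <- c(cardiac_freq, resp_freq, mayer_freq)
  if (any(fr <= 0)) stop("noise frequencies must be positive")
  amps <- c(cardiac_amp, resp_amp, mayer_amp, white_sd,
            motion_spike_amp)
  if (any(amps < 0)) stop("noise amplitudes must be non-negative")
  structure(list(cardiac_freq = cardiac_freq, resp_freq = resp_freq,
                 mayer_freq = mayer_freq, cardiac_amp = cardiac_amp,
                 resp_amp = resp_amp, mayer_amp = mayer_amp,
                 drift_slope = drift_slope, white_sd = white_sd,
                 motion_spike_rate = motion_spike_rate,
                 motion_spike_amp = motion_spike_amp,
                 motion_decay_s = motion_decay_s,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_params")
}

#' Session-wise learning profile
#'
#' Per-channel multipliers applied to the regulation-condition (control)
#' neural drive, session by session, emulating progressive self-regulatory
#' learning: in the default profile the affected channels' control response
#' rises over sessions 1-3 and plateaus at session 4, except S5-D5 which
#' keeps rising through session 4. Channels not listed have multiplier 1;
#' sessions beyond the profile hold the last value.
#'
#' @param multipliers named list: channel label -> numeric vector of
#'   session multipliers (all > 0).
#' @return Object of class `learning_profile`.
#' @export
learning_profile <- function(multipliers = list(
  `S3-D2` = c(1, 1.5, 2.0, 2.05),
  `S3-D5` = c(1, 1.5, 2.0, 2.05),
  `S5-D4` = c(1, 1.5, 2.0, 2.05),
  `S5-D5` = c(1, 1.4, 1.8, 2.3))) {
  if (any(unlist(multipliers) <= 0)) stop("multipliers must be positive")
  structure(list(multipliers = multipliers,
                 affected_channels = names(multipliers)),
            class = "learning_profile")
}

#' @rdname learning_profile
#' @export
flat_learning_profile <- function() {
  learning_profile(list(`S3-D2` = 1, `S3-D5` = 1, `S5-D4` = 1, `S5-D5` = 1))
}

# Restrict a learning profile to the channels of a (possibly reduced)
# montage; callers working montage-wide keep strict label validation.
prune_profile <- function(learning, montage) {
  keep <- intersect(learning$affected_channels, montage$channels$label)
  learning_profile(learning$multipliers[keep])
}

profile_multiplier <- function(learning, channel, session_index) {
  m <- learning$multipliers[[channel]]
  if (is.null(m)) return(1)
  m[min(session_index, length(m))]
}

#' Simulate ground-truth chromophore concentration changes
#'
#' Convolves the session's neural design with the canonical HRF kernel. The
#' session/channel learning multiplier scales the regulation-condition
#' component of the drive; the induction component is unchanged. HbR is a
#' fixed negative multiple of HbO (neurovascular anticorrelation).
#'
#' @param design split design matrix from
#'   `neural_design(..., split = TRUE)`.
#' @param hrf an [hrf_params()].
#' @param learning a [learning_profile()].
#' @param session_index session number.
#' @param montage an [fnirs_montage()].
#' @param sampling_rate Hz.
#' @param amplitude steady-state HbO response to a sustained unit design
#'   drive, in mol/L (default 2 micromolar, a plausible prefrontal task-evoked fNIRS
#'   response); the HRF convolution is normalised to unit DC gain.
#' @return List with `hbo` and `hbr`: channel x time matrices (mol/L), with
#'   channel labels as rownames.
#' @export
simulate_concentrations <- function(design, hrf = hrf_params(),
                                    learning = learning_profile(),
                                    session_index = 1,
                                    montage = default_montage(),
                                    sampling_rate = 10.2,
                                    amplitude = 2e-6) {
  if (is.null(dim(design)))
    design <- cbind(induction = design, regulation = numeric(length(design)))
  bad <- setdiff(learning$affected_channels, montage$channels$label)
  if (length(bad))
    stop("learning profile names channel(s) absent from the montage: ",
         paste(bad, collapse = ", "))
  k <- canonical_hrf(hrf, sampling_rate)
  k <- k / sum(k)  # unit DC gain: sustained unit drive -> unit plateau
  n <- nrow(design)
  conv_ind <- fft_convolve(design[, "induction"], k)[seq_len(n)]
  conv_reg <- fft_convolve(design[, "regulation"], k)[seq_len(n)]
  labels <- montage$channels$label
  hbo <- matrix(0, nrow = length(labels), ncol = n,
                dimnames = list(labels, NULL))
  for (ch in labels) {
    m <- profile_multiplier(learning, ch, session_index)
    hbo[ch, ] <- amplitude * (conv_ind + m * conv_reg)
  }
  list(hbo = hbo, hbr = hrf$hbr_scale * hbo)
}

#' Forward modified Beer-Lambert model
#'
#' Maps chromophore concentration changes to optical-density changes at the
#' two wavelengths: `dOD(lambda) = (eps_HbO(lambda) dHbO +
#' eps_HbR(lambda) dHbR) * L * DPF(lambda)`, with `L` the source-detector
#' separation in cm. Exact linear map; inverted by [mbll_invert()].
#'
#' @param concentrations list with `hbo`, `hbr` channel x time matrices.
#' @param mbll an [mbll_params()].
#' @param montage an [fnirs_montage()] supplying per-channel separations.
#' @return List of channel x time matrices, one per wavelength
#'   (`od760`, `od850`).
#' @export
forward_mbll <- function(concentrations, mbll = mbll_params(),
                         montage = default_montage()) {
  E <- mbll$extinction
  if (abs(det(E)) < .Machine$double.eps * max(abs(E))^2)
    stop("extinction matrix is singular; cannot form the MBLL map")
  sep_cm <- montage$channels$separation_mm / 10
  names(sep_cm) <- montage$channels$label
  labels <- rownames(concentrations$hbo)
  od <- lapply(1:2, function(w) {
    L <- sep_cm[labels] * mbll$dpf[w]
    (E[w, "hbo"] * concentrations$hbo +
       E[w, "hbr"] * concentrations$hbr) * L
  })
  names(od) <- paste0("od", rownames(E))
  od
}

# OD-scale noise shared across wavelengths where physiology is shared
# (oscillation phases, motion timing); white noise independent per wavelength.
make_od_noise <- function(n, sampling_rate, noise, seed) {
  t <- (seq_len(n) - 1) / sampling_rate
  with_seed(seed, {
    phases <- stats::runif(3, 0, 2 * pi)
    osc <- noise$cardiac_amp * sin(2 * pi * noise$cardiac_freq * t + phases[1]) +
      noise$resp_amp * sin(2 * pi * noise$resp_freq * t + phases[2]) +
      noise$mayer_amp * sin(2 * pi * noise$mayer_freq * t + phases[3])
    drift <- noise$drift_slope * t
    n_spikes <- stats::rpois(1, noise$motion_spike_rate * max(t) / 60)
    spikes <- numeric(n)
    if (n_spikes > 0 && noise$motion_spike_amp > 0) {
      onsets <- sort(stats::runif(n_spikes, 0, max(t)))
      signs <- sample(c(-1, 1), n_spikes, replace = TRUE)
      for (k in seq_len(n_spikes)) {
        i0 <- floor(onsets[k] * sampling_rate) + 1
        idx <- i0:n
        spikes[idx] <- spikes[idx] + signs[k] * noise$motion_spike_amp *
          exp(-(t[idx] - t[i0]) / noise$motion_decay_s)
      }
    }
    shared <- osc + drift + spikes
    list(w1 = shared + stats::rnorm(n, 0, noise$white_sd),
         w2 = shared + stats::rnorm(n, 0, noise$white_sd))
  })
}

#' Synthesise raw detector intensities from clean optical density
#'
#' `I(t) = baseline_intensity * 10^-(od_clean(t) + od_noise(t))`; the noise
#' adds sinusoidal physiological components, slow drift, white noise and
#' seeded motion spikes on the OD (log-intensity) scale, so intensities are
#' strictly positive for any finite draw.
#'
#' @param od_clean list of per-wavelength channel x time OD matrices.
#' @param noise a [noise_params()].
#' @param baseline_intensity detector units at rest (> 0).
#' @param sampling_rate Hz.
#' @return List of channel x time intensity matrices per wavelength.
#' @export
synthesize_intensity <- function(od_clean, noise = noise_params(),
                                 baseline_intensity = 1000,
                                 sampling_rate = 10.2) {
  if (baseline_intensity <= 0) stop("baseline_intensity must be positive")
  labels <- rownames(od_clean[[1]])
  n <- ncol(od_clean[[1]])
  out <- lapply(od_clean, function(m) m)
  for (i in seq_along(labels)) {
    nz <- make_od_noise(n, sampling_rate, noise,
                        derive_seed(noise$rng_seed, "noise", i))
    out[[1]][i, ] <- baseline_intensity *
      10^(-(od_clean[[1]][i, ] + nz$w1))
    out[[2]][i, ] <- baseline_intensity *
      10^(-(od_clean[[2]][i, ] + nz$w2))
  }
  out
}

#' Simulate one session's raw two-wavelength recording
#'
#' Chains the neural design, canonical HRF convolution, learning-profile
#' scaling, the forward modified Beer-Lambert map and intensity synthesis
#' with physiological noise, retaining the ground-truth concentrations.
#'
#' @param timeline the session event timeline (stimuli optional).
#' @param session_index session number (drives the learning profile).
#' @param montage,hrf,noise,learning,mbll component parameter objects.
#' @param gains induction/regulation design gains.
#' @param sampling_rate Hz (default 10.2).
#' @param amplitude steady-state HbO response to a sustained unit drive
#'   (mol/L).
#' @param pad_s seconds of resting pre/post-roll around the protocol.
#' @return Object of class `nirs_recording`: sampling metadata, wavelengths
#'   (760, 850 nm), `intensity` (per-wavelength channel x time matrices),
#'   the montage, the timeline, and `ground_truth` concentrations.
#' @export
simulate_session <- function(timeline, session_index = attr(timeline, "session_index"),
                             montage = default_montage(),
                             hrf = hrf_params(),
                             noise = noise_params(),
                             learning = learning_profile(),
                             mbll = mbll_params(),
                             gains = c(induction = 1, regulation = 0.6),
                             sampling_rate = 10.2,
                             amplitude = 2e-6,
                             pad_s = 0) {
  design <- neural_design(timeline, gains, sampling_rate, split = TRUE)
  conc <- simulate_concentrations(design, hrf,
                                  prune_profile(learning, montage),
                                  session_index, montage, sampling_rate,
                                  amplitude)
  if (pad_s > 0) {
    npad <- round(pad_s * sampling_rate)
    padm <- function(m) cbind(matrix(0, nrow(m), npad), m,
                              matrix(0, nrow(m), npad))
    conc$hbo <- padm(conc$hbo); conc$hbr <- padm(conc$hbr)
  }
  od <- forward_mbll(conc, mbll, montage)
  intensity <- synthesize_intensity(od, noise,
                                    sampling_rate = sampling_rate)
  structure(list(sampling_rate = sampling_rate,
                 wavelengths = c(760, 850),
                 intensity = intensity,
                 montage = montage,
                 timeline = timeline,
                 pad_s = pad_s,
                 session_index = session_index,
                 ground_truth = conc),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("fNIRS recording: session %d, %d channels x 2 wavelengths (%d/%d nm), %d samples @ %.1f Hz\n",
              x$session_index, nrow(x$intensity[[1]]), x$wavelengths[1],
              x$wavelengths[2], ncol(x$intensity[[1]]), x$sampling_rate))
  invisible(x)
}

#' Simulate a multi-session training programme
#'
#' One recording per session, with per-session noise seeds derived
#' deterministically from the top-level seed so partial reruns agree with
#' full runs. Stimuli are assigned across the whole programme first.
#'
#' @param config a [protocol_config()].
#' @param n_sessions sessions to simulate (<= `config$n_sessions`); the
#'   published proof-of-concept used 4, a compact version of the 8-session
#'   programme.
#' @param seed top-level integer seed.
#' @inheritParams simulate_session
#' @return List of `nirs_recording`, one per session.
#' @export
simulate_programme <- function(config = protocol_config(),
                               n_sessions = 4, seed = 1L,
                               montage = default_montage(),
                               hrf = hrf_params(),
                               noise = noise_params(),
                               learning = learning_profile(),
                               mbll = mbll_params(),
                               gains = c(induction = 1, regulation = 0.6),
                               sampling_rate = 10.2, amplitude = 2e-6,
                               pad_s = 0) {
  if (n_sessions > config$n_sessions)
    stop("n_sessions exceeds the configured programme length")
  timelines <- build_programme(config, seed = derive_seed(seed, "stimuli"))
  lapply(seq_len(n_sessions), function(s) {
    ns <- noise
    ns$rng_seed <- derive_seed(seed, "session", s)
    simulate_session(timelines[[s]], session_index = s, montage = montage,
                     hrf = hrf, noise = ns, learning = learning, mbll = mbll,
                     gains = gains, sampling_rate = sampling_rate,
                     amplitude = amplitude, pad_s = pad_s)
  })
}
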