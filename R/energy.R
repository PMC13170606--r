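#' Extract fixed-length epochs at event onsets
#'
#' Cuts 15-s (by default) windows starting at every stressor
#' (induction-prompt) and control (regulation-prompt) event onset, for every
#' channel and chromophore. Epochs that would run past the end of the
#' recording are discarded and counted.
#'
#' @param series a `nirs_hemo` from [preprocess_pipeline()].
#' @param timeline event timeline; defaults to the one carried by `series`.
#' @param epoch_duration seconds (default 15).
#' @param condition_map named character vector mapping event types to
#'   condition labels.
#' @return List with `epochs` (a list of epoch records: channel,
#'   chromophore, condition, onset, session, samples) and `n_discarded`.
#' @export
extract_epochs <- function(series, timeline = series$timeline,
                           epoch_duration = 15,
                           condition_map = c(induction_prompt = "stressor",
                                             regulation_prompt = "control")) {
  if (is.null(timeline) || nrow(timeline) == 0)
    stop("timeline is empty; nothing to epoch")
  fs <- series$sampling_rate
  len <- round(epoch_duration * fs)
  ev <- timeline[timeline$event_type %in% names(condition_map), , drop = FALSE]
  n <- ncol(series$hbo)
  epochs <- list()
  n_discarded <- 0L
  for (r in seq_len(nrow(ev))) {
    start <- round(ev$onset[r] * fs) + 1L
    if (start + len - 1L > n) { n_discarded <- n_discarded + 1L; next }
    idx <- start:(start + len - 1L)
    for (chrom in c("hbo", "hbr")) {
      mat <- series[[chrom]]
      for (ch in series$channels) {
        epochs[[length(epochs) + 1L]] <- list(
          channel = ch, chromophore = chrom,
          condition = unname(condition_map[ev$event_type[r]]),
          onset = ev$onset[r],
          session = series$session_index,
          samples = mat[ch, idx])
      }
    }
  }
  list(epochs = epochs, n_discarded = n_discarded)
}

#' Signal energy of an epoch
#'
#' The sum of squared sample values over the epoch window — the discrete
#' signal energy, restricted to the epoch's samples.
#'
#' @param samples numeric vector of epoch samples (or an epoch record).
#' @return Non-negative scalar energy.
#' @export
epoch_energy <- function(samples) {
  if (is.list(samples)) samples <- samples$samples
  if (!length(samples)) stop("empty epoch")
  sum(samples^2)
}

#' Epoch-to-mean energy ratios
#'
#' For every epoch, its energy divided by the mean epoch energy of its
#' (channel, chromophore, session) group, both conditions pooled, making
#' the ratio a within-session relative activation measure whose group mean
#' is exactly 1.
#'
#' @param epochs list of epoch records from [extract_epochs()].
#' @param denominator `"pooled"` (both conditions; default) or
#'   `"condition"` (each condition normalised by its own mean).
#' @return Data frame with columns channel, chromophore, session,
#'   condition, epoch_index, onset, energy, ratio.
#' @export
energy_ratios <- function(epochs, denominator = c("pooled", "condition")) {
  denominator <- match.arg(denominator)
  if (!length(epochs)) stop("no epochs supplied")
  df <- data.frame(
    channel = vapply(epochs, `[[`, "", "channel"),
    chromophore = vapply(epochs, `[[`, "", "chromophore"),
    session = vapply(epochs, function(e) as.integer(e$session), 1L),
    condition = vapply(epochs, `[[`, "", "condition"),
    onset = vapply(epochs, function(e) as.numeric(e$onset), 1),
    energy = vapply(epochs, function(e) epoch_energy(e$samples), 1)
  )
  key <- if (denominator == "pooled")
    interaction(df$channel, df$chromophore, df$session, drop = TRUE)
  else
    interaction(df$channel, df$chromophore, df$session, df$condition,
                drop = TRUE)
  gm <- tapply(df$energy, key, mean)
  if (any(gm == 0))
    stop("degenerate group with zero mean energy (all-zero signal)")
  df$ratio <- as.numeric(df$energy / gm[as.character(key)])
  df <- df[order(df$channel, df$chromophore, df$session, df$onset), ]
  df$epoch_index <- stats::ave(df$ratio, df$channel, df$chromophore,
                               df$session, FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' Average ratios within event type
#'
#' Arithmetic mean of the epoch-to-mean energy ratios per
#' (channel, chromophore, session, condition) — the per-event average.
#'
#' @param records data frame from [energy_ratios()].
#' @return Data frame with columns channel, chromophore, session,
#'   condition, n_epochs, mean_ratio.
#' @export
average_by_event <- function(records) {
  if (!nrow(records)) stop("no records supplied")
  agg <- stats::aggregate(ratio ~ channel + chromophore + session + condition,
                          data = records, FUN = mean)
  names(agg)[names(agg) == "ratio"] <- "mean_ratio"
  cnt <- stats::aggregate(ratio ~ channel + chromophore + session + condition,
                          data = records, FUN = length)
  agg$n_epochs <- cnt$ratio
  agg[order(agg$channel, agg$chromophore, agg$session, agg$condition),
      c("channel", "chromophore", "session", "condition",
        "n_epochs", "mean_ratio")]
}

#' Five-number session summaries of energy ratios
#'
#' Boxplot statistics (quartiles, median, whisker bounds at 1.5 IQR) of the
#' ratios per channel x chromophore x session x condition.
#'
#' @param records data frame from [energy_ratios()].
#' @param channels optional channel filter.
#' @return Data frame of summaries.
#' @export
summarize_sessions <- function(records, channels = NULL) {
  if (!is.null(channels)) {
    unknown <- setdiff(channels, unique(records$channel))
    if (length(unknown))
      stop("unknown channel(s): ", paste(unknown, collapse = ", "),
           "; available: ", paste(sort(unique(records$channel)),
                                  collapse = ", "))
    records <- records[records$channel %in% channels, , drop = FALSE]
  }
  key <- interaction(records$channel, records$chromophore,
                     records$session, records$condition, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    q <- stats::quantile(g$ratio, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(channel = g$channel[1], chromophore = g$chromophore[1],
               session = g$session[1], condition = g$condition[1],
               n_epochs = nrow(g), mean_ratio = mean(g$ratio),
               q1 = q[1], median = q[2], q3 = q[3],
               whisker_low = max(min(g$ratio), q[1] - 1.5 * iqr),
               whisker_high = min(max(g$ratio), q[3] + 1.5 * iqr))
  }))
  out <- out[order(out$channel, out$chromophore, out$session,
                   out$condition), ]
  rownames(out) <- NULL
  out
}

#' Classify the across-session trend of per-session means
#'
#' Rule-based classification of a sequence of per-session mean ratios.
#' Each session-over-session increment is labelled up, flat or down with a
#' plateau tolerance `delta` (relative to the previous mean; default 5%).
#' All ups = `rising_throughout`; all flats = `flat`; ups followed only by
#' flats with no downs = `rising_then_plateau`; anything else = `other`.
#'
#' @param means numeric vector of per-session means (length >= 3).
#' @param delta plateau tolerance as a fraction of the previous mean.
#' @return One of `"rising_then_plateau"`, `"rising_throughout"`,
#'   `"flat"`, `"other"`.
#' @export
classify_trend <- function(means, delta = 0.05) {
  if (length(means) < 3)
    stop("need at least 3 sessions of means to classify a trend")
  d <- diff(means) / means[-length(means)]
  lab <- ifelse(d > delta, "up", ifelse(d < -delta, "down", "flat"))
  if (all(lab == "up")) return("rising_throughout")
  if (all(lab == "flat")) return("flat")
  if (!any(lab == "down") && any(lab == "up") && any(lab == "flat") &&
      max(which(lab == "up")) < min(which(lab == "flat")))
    return("rising_then_plateau")
  "other"
}

#' Energy-ratio analysis of a full training programme
#'
#' Runs the preprocessing chain and the epoch-to-mean energy-ratio analysis
#' over every session of a simulated or recorded programme, returning a
#' fitted-analysis object with print, summary and plot methods.
#'
#' @param recordings list of `nirs_recording` (one per session), or a list
#'   of preprocessed `nirs_hemo` objects.
#' @param epoch_duration epoch length in seconds.
#' @param channels optional channel restriction for summaries/plots.
#' @param chromophore default chromophore for summaries and trend
#'   classification (`"hbo"`; HbR is analysed in parallel).
#' @param fspec,wspec,mbll preprocessing parameters (ignored for
#'   already-preprocessed input).
#' @param trend_delta plateau tolerance for [classify_trend()].
#' @return Object of class `nf_energy` with elements `records` (per-epoch
#'   tidy table), `event_means`, `summary`, `trends` (per channel, on the
#'   control-condition means of the default chromophore), `n_discarded`.
#' @export
analyze_programme <- function(recordings, epoch_duration = 15,
                              channels = NULL, chromophore = "hbo",
                              fspec = filter_spec(), wspec = wavelet_spec(),
                              mbll = mbll_params(), trend_delta = 0.05) {
  hemo <- lapply(recordings, function(r) {
    if (inherits(r, "nirs_hemo")) r
    else preprocess_pipeline(r, fspec, wspec, mbll)
  })
  all_epochs <- list(); n_disc <- 0L
  for (h in hemo) {
    ep <- extract_epochs(h, epoch_duration = epoch_duration)
    all_epochs <- c(all_epochs, ep$epochs)
    n_disc <- n_disc + ep$n_discarded
  }
  records <- energy_ratios(all_epochs)
  ev_means <- average_by_event(records)
  smry <- summarize_sessions(records, channels)
  sel <- ev_means[ev_means$chromophore == chromophore &
                    ev_means$condition == "control", ]
  trends <- vapply(split(sel, sel$channel), function(g) {
    g <- g[order(g$session), ]
    if (nrow(g) >= 3) classify_trend(g$mean_ratio, trend_delta)
    else NA_character_
  }, "")
  structure(list(records = records, event_means = ev_means,
                 summary = smry, trends = trends,
                 chromophore = chromophore, trend_delta = trend_delta,
                 epoch_duration = epoch_duration,
                 n_discarded = n_disc),
            class = "nf_energy")
}

#' @export
print.nf_energy <- function(x, ...) {
  ns <- length(unique(x$records$session))
  cat(sprintf("Energy-ratio analysis: %d sessions, %d channels, %d epochs (%d discarded)\n",
              ns, length(unique(x$records$channel)),
              nrow(x$records) / 2, x$n_discarded))
  cat(sprintf("Control-condition %s trends (plateau tolerance %.0f%%):\n",
              toupper(x$chromophore), 100 * x$trend_delta))
  tr <- x$trends[!is.na(x$trends)]
  for (ch in names(tr)) cat(sprintf("  %-8s %s\n", ch, tr[ch]))
  invisible(x)
}

#' @export
summary.nf_energy <- function(object, ...) {
  object$summary
}

#' Boxplots of energy ratio per session
#'
#' One panel per channel: boxplots of the epoch-to-mean energy ratio by
#' session for the chosen condition and chromophore, mirroring the standard
#' presentation of session-wise neurofeedback learning curves.
#'
#' @param x an `nf_energy` object.
#' @param channels channels to plot (default: all, up to 4).
#' @param condition `"control"` or `"stressor"`.
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.nf_energy <- function(x, channels = NULL, condition = "control",
                           chromophore = x$chromophore, ...) {
  rec <- x$records[x$records$condition == condition &
                     x$records$chromophore == chromophore, ]
  if (is.null(channels)) channels <- utils::head(sort(unique(rec$channel)), 4)
  op <- graphics::par(mfrow = c(ceiling(length(channels) / 2),
                                min(2, length(channels))))
  on.exit(graphics::par(op))
  for (ch in channels) {
    g <- rec[rec$channel == ch, ]
    graphics::boxplot(ratio ~ session, data = g,
                      main = ch, xlab = "Session",
                      ylab = "Energy ratio", col = "grey85", ...)
  }
  invisible(x)
}
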