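#' Write a session timeline as a BIDS-style events.tsv
#'
#' Columns: `onset` (s), `duration` (s), `trial_type`, `block`, `stim_id`;
#' tab-separated, dot decimal, `n/a` for missing values.
#'
#' @param timeline an event timeline.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(timeline, path) {
  df <- data.frame(onset = timeline$onset, duration = timeline$duration,
                   trial_type = timeline$event_type,
                   block = ifelse(is.na(timeline$block), "n/a",
                                  as.character(timeline$block)),
                   stim_id = ifelse(is.na(timeline$stim_id), "n/a",
                                    timeline$stim_id))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, dec = ".")
  invisible(path)
}

.known_trial_types <- c("baseline", "contextualisation",
                        "induction_prompt", "regulation_prompt")

#' Read a BIDS-style events.tsv into an event timeline
#'
#' @param path events.tsv file with columns `onset`, `duration`,
#'   `trial_type` (and optionally `block`, `stim_id`).
#' @param session_index,stage metadata to attach.
#' @return An `event_timeline`.
#' @export
read_events <- function(path, session_index = NA_integer_,
                        stage = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (nrow(df) == 0) stop("events file is empty: ", path)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("events file missing column(s): ", paste(miss, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric %s at row %d (dot-decimal required): '%s'",
                   col, bad[1], df[[col]][bad[1]]))
    v
  }
  onset <- num("onset"); duration <- num("duration")
  unknown <- which(!df$trial_type %in% .known_trial_types)
  if (length(unknown))
    stop(sprintf("unknown trial_type '%s' at row %d",
                 df$trial_type[unknown[1]], unknown[1]))
  blk <- if ("block" %in% names(df))
    suppressWarnings(as.integer(ifelse(df$block == "n/a", NA, df$block)))
  else rep(NA_integer_, nrow(df))
  sid <- if ("stim_id" %in% names(df))
    ifelse(df$stim_id == "n/a", NA_character_, df$stim_id)
  else rep(NA_character_, nrow(df))
  ev <- data.frame(onset = onset, duration = duration,
                   event_type = df$trial_type, block = blk, stim_id = sid)
  ev <- ev[order(ev$onset), ]
  rownames(ev) <- NULL
  structure(ev, session_index = session_index, stage = stage,
            total_duration = max(ev$onset + ev$duration),
            class = c("event_timeline", "data.frame"))
}

#' Write / read a raw recording as wide CSV plus JSON sidecar
#'
#' The intensity matrix is written as a wide CSV (columns `time_s`, then
#' `<channel>_<wavelength>`); sampling rate, wavelengths, montage, session
#' index and padding go into a JSON sidecar next to it; the session events
#' into an events.tsv; ground truth (when present) into its own CSV.
#'
#' @param recording a `nirs_recording`.
#' @param dir output directory (created if needed).
#' @param stem file stem, e.g. `"session1"`.
#' @return The sidecar path, invisibly.
#' @export
write_recording <- function(recording, dir, stem) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- recording$sampling_rate
  n <- ncol(recording$intensity[[1]])
  labels <- rownames(recording$intensity[[1]])
  wide <- data.frame(time_s = (seq_len(n) - 1) / fs)
  for (w in 1:2)
    for (ch in labels)
      wide[[sprintf("%s_%d", ch, recording$wavelengths[w])]] <-
        recording$intensity[[w]][ch, ]
  int_path <- file.path(dir, paste0(stem, "_intensity.csv"))
  utils::write.csv(wide, int_path, row.names = FALSE)
  write_events_tsv(recording$timeline,
                   file.path(dir, paste0(stem, "_events.tsv")))
  if (!is.null(recording$ground_truth)) {
    gt <- data.frame(time_s = (seq_len(ncol(recording$ground_truth$hbo)) - 1) / fs)
    for (ch in rownames(recording$ground_truth$hbo)) {
      gt[[paste0(ch, "_hbo")]] <- recording$ground_truth$hbo[ch, ]
      gt[[paste0(ch, "_hbr")]] <- recording$ground_truth$hbr[ch, ]
    }
    utils::write.csv(gt, file.path(dir, paste0(stem, "_groundtruth.csv")),
                     row.names = FALSE)
  }
  sidecar <- list(sampling_rate = fs,
                  wavelengths = recording$wavelengths,
                  session_index = recording$session_index,
                  pad_s = recording$pad_s,
                  n_samples = n,
                  montage = recording$montage$channels[
                    c("source", "detector", "separation_mm", "region")])
  sc_path <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(sidecar, sc_path, auto_unbox = TRUE, digits = NA)
  invisible(sc_path)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir, stem) {
  sc_path <- file.path(dir, paste0(stem, ".json"))
  if (!file.exists(sc_path))
    stop("missing JSON sidecar ", sc_path,
         "; regenerate the recording with write_recording()")
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  wide <- utils::read.csv(file.path(dir, paste0(stem, "_intensity.csv")),
                          check.names = FALSE)
  if (nrow(wide) != sc$n_samples)
    stop(sprintf("sidecar/sample-count mismatch: sidecar says %d, CSV has %d",
                 sc$n_samples, nrow(wide)))
  mont <- fnirs_montage(as.data.frame(sc$montage))
  labels <- mont$channels$label
  intensity <- lapply(sc$wavelengths, function(w) {
    m <- t(as.matrix(wide[, sprintf("%s_%d", labels, w), drop = FALSE]))
    dimnames(m) <- list(labels, NULL)
    m
  })
  timeline <- read_events(file.path(dir, paste0(stem, "_events.tsv")),
                          session_index = sc$session_index)
  gt_path <- file.path(dir, paste0(stem, "_groundtruth.csv"))
  gt <- NULL
  if (file.exists(gt_path)) {
    g <- utils::read.csv(gt_path, check.names = FALSE)
    gt <- list(hbo = t(as.matrix(g[, paste0(labels, "_hbo"), drop = FALSE])),
               hbr = t(as.matrix(g[, paste0(labels, "_hbr"), drop = FALSE])))
    dimnames(gt$hbo) <- dimnames(gt$hbr) <- list(labels, NULL)
  }
  structure(list(sampling_rate = sc$sampling_rate,
                 wavelengths = as.numeric(sc$wavelengths),
                 intensity = intensity, montage = mont,
                 timeline = timeline, pad_s = sc$pad_s,
                 session_index = sc$session_index,
                 ground_truth = gt),
            class = "nirs_recording")
}

#' Write preprocessed hemodynamics as long-format CSV
#'
#' Columns: channel, chromophore, time_s, value.
#'
#' @param hemo a `nirs_hemo`.
#' @param path output CSV path.
#' @export
write_hemo_csv <- function(hemo, path) {
  n <- ncol(hemo$hbo)
  t_s <- (seq_len(n) - 1) / hemo$sampling_rate
  long <- do.call(rbind, lapply(c("hbo", "hbr"), function(cr)
    do.call(rbind, lapply(hemo$channels, function(ch)
      data.frame(channel = ch, chromophore = cr, time_s = t_s,
                 value = hemo[[cr]][ch, ])))))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' End-to-end run configuration
#'
#' A single serialisable document holding the seed and every stage's
#' parameters; round-trips through YAML.
#'
#' @param seed top-level integer seed.
#' @param n_sessions sessions to simulate and analyse.
#' @param out_dir output directory.
#' @param channels montage restriction (`NULL` = full default montage).
#' @param config,noise,learning,fspec,wspec,mbll,gains stage parameters.
#' @param epoch_duration analysis epoch length (s).
#' @param feedback optional [feedback_config()] (`NULL` disables the
#'   feedback stage).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_sessions = 4, out_dir = tempfile("nfrun"),
                       channels = NULL,
                       config = protocol_config(),
                       noise = noise_params(),
                       learning = learning_profile(),
                       fspec = filter_spec(), wspec = wavelet_spec(),
                       mbll = mbll_params(),
                       gains = c(induction = 1, regulation = 0.6),
                       epoch_duration = 15,
                       feedback = NULL) {
  structure(list(seed = as.integer(seed), n_sessions = n_sessions,
                 out_dir = out_dir, channels = channels,
                 protocol = config, noise = noise, learning = learning,
                 fspec = fspec, wspec = wspec, mbll = mbll, gains = gains,
                 epoch_duration = epoch_duration, feedback = feedback),
            class = "run_config")
}

#' Serialise / deserialise a run configuration as YAML
#'
#' @param rc a [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(rc, path) {
  strip <- function(x) {
    if (is.list(x)) { x <- lapply(x, strip); attributes(x) <- list(names = names(x)) }
    if (is.matrix(x)) x <- list(.matrix = as.numeric(x), .dim = dim(x),
                                .dimnames = dimnames(x))
    x
  }
  yaml::write_yaml(strip(unclass(rc)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unmat <- function(x) {
    if (is.list(x) && !is.null(x$.matrix))
      return(matrix(x$.matrix, nrow = x$.dim[[1]], dimnames = x$.dimnames))
    if (is.list(x)) return(lapply(x, unmat))
    x
  }
  raw <- unmat(raw)
  pc <- do.call(protocol_config, raw$protocol[
    setdiff(names(raw$protocol), "block_duration")])
  pc$stage_map <- unlist(raw$protocol$stage_map)
  run_config(seed = raw$seed, n_sessions = raw$n_sessions,
             out_dir = raw$out_dir,
             channels = if (length(raw$channels)) unlist(raw$channels),
             config = pc,
             noise = do.call(noise_params, raw$noise),
             learning = learning_profile(lapply(raw$learning$multipliers,
                                                unlist)),
             fspec = filter_spec(raw$fspec$order, unlist(raw$fspec$band),
                                 raw$fspec$window),
             wspec = wavelet_spec(raw$wspec$family, raw$wspec$levels,
                                  unlist(raw$wspec$removed_details)),
             mbll = mbll_params(unlist(raw$mbll$dpf), raw$mbll$extinction,
                                raw$mbll$separation_cm),
             gains = unlist(raw$gains),
             epoch_duration = raw$epoch_duration,
             feedback = if (!is.null(raw$feedback))
               do.call(feedback_config, lapply(raw$feedback, function(v)
                 if (length(v) > 1) unlist(v) else v)))
}

#' Run the full pipeline end to end
#'
#' schedule -> simulate -> preprocess -> analyze (-> feedback), writing
#' every artifact under `rc$out_dir` and returning a manifest of output
#' files with content hashes. Identical configuration and seed produce
#' identical hashes.
#'
#' @param rc a [run_config()].
#' @param figures if `TRUE`, also render per-channel boxplot figures (PDF).
#' @return Invisibly, a list with `manifest` (data frame of file, md5),
#'   `analysis` (the `nf_energy` object) and `out_dir`.
#' @export
run_all <- function(rc = run_config(), figures = FALSE) {
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  montage <- default_montage(rc$channels)
  recs <- simulate_programme(config = rc$protocol,
                             n_sessions = rc$n_sessions, seed = rc$seed,
                             montage = montage, noise = rc$noise,
                             learning = rc$learning, mbll = rc$mbll,
                             gains = rc$gains)
  for (s in seq_along(recs))
    write_recording(recs[[s]], rc$out_dir, sprintf("session%d", s))
  hemo <- lapply(recs, preprocess_pipeline,
                 fspec = rc$fspec, wspec = rc$wspec, mbll = rc$mbll)
  for (s in seq_along(hemo))
    write_hemo_csv(hemo[[s]],
                   file.path(rc$out_dir, sprintf("session%d_hemo.csv", s)))
  ana <- analyze_programme(hemo, epoch_duration = rc$epoch_duration)
  utils::write.csv(ana$records, file.path(rc$out_dir, "energy_ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(ana$summary, file.path(rc$out_dir, "session_summary.csv"),
                   row.names = FALSE)
  if (!is.null(rc$feedback)) {
    tls <- lapply(recs, function(r) r$timeline)
    fb <- run_closed_loop(tls, config = rc$feedback, seed = rc$seed)
    for (s in seq_along(fb))
      utils::write.csv(fb[[s]]$trace,
                       file.path(rc$out_dir,
                                 sprintf("session%d_thermometer.csv", s)),
                       row.names = FALSE)
  }
  if (figures) {
    grDevices::pdf(file.path(rc$out_dir, "energy_ratio_boxplots.pdf"),
                   width = 8, height = 6)
    plot(ana)
    grDevices::dev.off()
  }
  files <- sort(list.files(rc$out_dir, full.names = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  invisible(list(manifest = manifest, analysis = ana, out_dir = rc$out_dir))
}
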