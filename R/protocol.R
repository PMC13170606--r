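#' Training-programme protocol configuration
#'
#' Collects every timing and counting parameter of a block-design
#' neurofeedback training programme. A session is baseline (resting state),
#' then a contextualisation narrative, then active training made of
#' consecutive blocks alternating a short anxiety-induction segment with a
#' longer self-regulation segment. Verbal prompts alternate at a fixed
#' interval inside each block.
#'
#' Defaults reproduce the published programme: 3 min baseline, 1 min
#' contextualisation, 5 blocks of 3 min (30 s induction + 2.5 min
#' regulation), prompts every 30 s, 8 biweekly sessions in four stages,
#' a stimulus pool of 40 induction and 200 control phrases, and a
#' 19-item graded-exposure hierarchy.
#'
#' @param baseline_duration seconds of resting-state baseline.
#' @param contextualisation_duration seconds of scenario narration.
#' @param n_blocks active-training blocks per session.
#' @param induction_duration seconds of induction at the start of each block.
#' @param regulation_duration seconds of regulation filling the rest of the block.
#' @param prompt_interval seconds between successive regulation prompts.
#' @param n_sessions number of sessions in the full programme.
#' @param stage_map named integer vector mapping stage name to the number of
#'   consecutive sessions it spans, in programme order.
#' @param n_induction_phrases,n_control_phrases stimulus pool sizes.
#' @param n_hierarchy_items length of the graded-exposure hierarchy.
#' @return An object of class `protocol_config`.
#' @examples
#' cfg <- protocol_config()
#' cfg$block_duration  # 180 s
#' @export
protocol_config <- function(baseline_duration = 180,
                            contextualisation_duration = 60,
                            n_blocks = 5,
                            induction_duration = 30,
                            regulation_duration = 150,
                            prompt_interval = 30,
                            n_sessions = 8,
                            stage_map = c(Adaptation = 2,
                                          `Symptom Identification` = 2,
                                          Refinement = 2,
                                          Conditioning = 2),
                            n_induction_phrases = 40,
                            n_control_phrases = 200,
                            n_hierarchy_items = 19) {
  if (baseline_duration < 0 || contextualisation_duration < 0)
    stop("baseline and contextualisation durations must be non-negative")
  if (n_blocks < 0 || n_blocks != round(n_blocks))
    stop("n_blocks must be a non-negative integer")
  if (n_blocks > 0 && (induction_duration <= 0 || regulation_duration <= 0))
    stop("induction and regulation durations must be positive")
  if (prompt_interval <= 0) stop("prompt_interval must be positive")
  if (n_sessions < 1) stop("n_sessions must be at least 1")
  if (sum(stage_map) != n_sessions)
    stage_map <- stats::setNames(rep(ceiling(n_sessions / length(stage_map)),
                                     length(stage_map)), names(stage_map))
  structure(list(
    baseline_duration = baseline_duration,
    contextualisation_duration = contextualisation_duration,
    n_blocks = n_blocks,
    block_duration = induction_duration + regulation_duration,
    induction_duration = induction_duration,
    regulation_duration = regulation_duration,
    prompt_interval = prompt_interval,
    n_sessions = n_sessions,
    stage_map = stage_map,
    n_induction_phrases = n_induction_phrases,
    n_control_phrases = n_control_phrases,
    n_hierarchy_items = n_hierarchy_items
  ), class = "protocol_config")
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("Neurofeedback protocol configuration\n")
  cat(sprintf("  sessions: %d (%s)\n", x$n_sessions,
              paste(names(x$stage_map), collapse = " > ")))
  cat(sprintf("  session: %ds baseline + %ds contextualisation + %d x %ds blocks\n",
              x$baseline_duration, x$contextualisation_duration,
              x$n_blocks, x$block_duration))
  cat(sprintf("  block: %ds induction + %ds regulation, prompts every %ds\n",
              x$induction_duration, x$regulation_duration, x$prompt_interval))
  cat(sprintf("  stimulus pools: %d induction / %d control phrases\n",
              x$n_induction_phrases, x$n_control_phrases))
  invisible(x)
}

stage_of_session <- function(config, session_index) {
  ends <- cumsum(config$stage_map)
  names(ends)[which(session_index <= ends)[1]]
}

#' Build the event timeline of one training session
#'
#' Lays out a session on a common clock starting at 0 s: one baseline event,
#' one contextualisation event, then for every active-training block one
#' `induction_prompt` at the block start and `regulation_prompt`s every
#' `prompt_interval` seconds from the end of the induction segment until the
#' block end (exclusive).
#'
#' @param config a [protocol_config()].
#' @param session_index 1-based session number.
#' @return An object of class `event_timeline`: a data frame with columns
#'   `onset`, `duration`, `event_type`, `block`, `stim_id`, and attributes
#'   `session_index`, `stage` and `total_duration` (seconds).
#' @examples
#' tl <- build_session_timeline(protocol_config(), 1)
#' attr(tl, "total_duration")  # 1140 s = 19 min
#' @export
build_session_timeline <- function(config, session_index) {
  stopifnot(inherits(config, "protocol_config"))
  if (session_index < 1 || session_index > config$n_sessions ||
      session_index != round(session_index))
    stop(sprintf("session_index must be an integer in 1..%d", config$n_sessions))

  ev <- list(data.frame(onset = 0, duration = config$baseline_duration,
                        event_type = "baseline", block = NA_integer_,
                        stim_id = NA_character_),
             data.frame(onset = config$baseline_duration,
                        duration = config$contextualisation_duration,
                        event_type = "contextualisation", block = NA_integer_,
                        stim_id = NA_character_))
  active_start <- config$baseline_duration + config$contextualisation_duration
  if (config$n_blocks > 0) {
    for (b in seq_len(config$n_blocks)) {
      b0 <- active_start + (b - 1) * config$block_duration
      ev[[length(ev) + 1L]] <- data.frame(
        onset = b0, duration = config$induction_duration,
        event_type = "induction_prompt", block = b, stim_id = NA_character_)
      # first prompt at the end of the induction segment, then every
      # prompt_interval until the block end (exclusive)
      n_reg <- floor(config$regulation_duration / config$prompt_interval)
      reg_onsets <- b0 + config$induction_duration +
        (seq_len(n_reg) - 1) * config$prompt_interval
      if (length(reg_onsets))
        ev[[length(ev) + 1L]] <- data.frame(
          onset = reg_onsets, duration = config$prompt_interval,
          event_type = "regulation_prompt", block = b,
          stim_id = NA_character_)
    }
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$onset, match(events$event_type,
             c("baseline", "contextualisation", "induction_prompt",
               "regulation_prompt"))), , drop = FALSE]
  rownames(events) <- NULL
  structure(events,
            session_index = session_index,
            stage = stage_of_session(config, session_index),
            total_duration = config$baseline_duration +
              config$contextualisation_duration +
              config$n_blocks * config$block_duration,
            class = c("event_timeline", "data.frame"))
}

#' @export
print.event_timeline <- function(x, ...) {
  cat(sprintf("Session %s timeline (stage: %s), total %d s, %d events\n",
              attr(x, "session_index"), attr(x, "stage"),
              attr(x, "total_duration"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more events\n")
  invisible(x)
}

#' Count induction and regulation prompts in a timeline
#'
#' @param timeline an [build_session_timeline()] result.
#' @return Named integer vector `c(n_induction =, n_regulation =)`.
#' @export
count_prompts <- function(timeline) {
  c(n_induction = sum(timeline$event_type == "induction_prompt"),
    n_regulation = sum(timeline$event_type == "regulation_prompt"))
}

#' Create a stimulus pool
#'
#' @param n_induction,n_control pool sizes (defaults match the published
#'   240-phrase pool: 40 anxiety-evoking + 200 regulation statements).
#' @param rng_seed integer seed controlling all stimulus randomisation.
#' @return Object of class `stimulus_pool` with `induction_ids`,
#'   `control_ids` and `rng_seed`.
#' @export
stimulus_pool <- function(n_induction = 40, n_control = 200, rng_seed = 1L) {
  structure(list(
    induction_ids = sprintf("IND%03d", seq_len(n_induction)),
    control_ids = sprintf("REG%03d", seq_len(n_control)),
    rng_seed = as.integer(rng_seed)
  ), class = "stimulus_pool")
}

#' Assign stimuli to prompts across a whole programme
#'
#' Implements controlled randomisation: phrases are drawn without replacement
#' from each pool with a seeded generator, stratified per session, so that no
#' phrase repeats anywhere in the programme (reducing habituation) and the
#' assignment is a deterministic function of the pool seed.
#'
#' @param config a [protocol_config()].
#' @param pool a [stimulus_pool()].
#' @param timelines list of session timelines.
#' @return The timelines with every prompt's `stim_id` filled in.
#' @export
assign_stimuli <- function(config, pool, timelines) {
  stopifnot(inherits(pool, "stimulus_pool"))
  n_ind <- sum(vapply(timelines, function(tl)
    sum(tl$event_type == "induction_prompt"), integer(1)))
  n_reg <- sum(vapply(timelines, function(tl)
    sum(tl$event_type == "regulation_prompt"), integer(1)))
  if (n_ind > length(pool$induction_ids))
    stop(sprintf("induction pool exhausted: %d prompts but only %d phrases",
                 n_ind, length(pool$induction_ids)))
  if (n_reg > length(pool$control_ids))
    stop(sprintf("control pool exhausted: %d prompts but only %d phrases",
                 n_reg, length(pool$control_ids)))
  ind_order <- with_seed(pool$rng_seed, sample(pool$induction_ids))
  reg_order <- with_seed(pool$rng_seed + 1L, sample(pool$control_ids))
  i <- 0L; r <- 0L
  lapply(timelines, function(tl) {
    is_ind <- tl$event_type == "induction_prompt"
    is_reg <- tl$event_type == "regulation_prompt"
    tl$stim_id[is_ind] <- ind_order[i + seq_len(sum(is_ind))]
    tl$stim_id[is_reg] <- reg_order[r + seq_len(sum(is_reg))]
    i <<- i + sum(is_ind); r <<- r + sum(is_reg)
    tl
  })
}

#' Rank a participant's graded-exposure hierarchy
#'
#' Sorts performance situations ascending by the participant's anxiety
#' rating, ties broken by input order (stable sort), so exposure can proceed
#' from the least to the most anxiety-provoking scenario.
#'
#' @param ratings data frame with columns `situation_id` and `anxiety_rating`.
#' @param participant_id identifier attached to the hierarchy.
#' @param n_items expected number of situations (default 19).
#' @param scale_range permissible ordinal rating range.
#' @return Object of class `exposure_hierarchy`.
#' @export
rank_hierarchy <- function(ratings, participant_id,
                           n_items = 19, scale_range = c(0, 10)) {
  if (!all(c("situation_id", "anxiety_rating") %in% names(ratings)))
    stop("ratings needs columns situation_id and anxiety_rating")
  if (nrow(ratings) != n_items)
    stop(sprintf("expected %d ratings, got %d", n_items, nrow(ratings)))
  if (any(ratings$anxiety_rating < scale_range[1] |
          ratings$anxiety_rating > scale_range[2]))
    stop("anxiety_rating out of declared scale range")
  # stable order: by rating, ties by situation_id
  o <- order(ratings$anxiety_rating, ratings$situation_id)
  structure(list(items = ratings[o, c("situation_id", "anxiety_rating")],
                 participant_id = participant_id),
            class = "exposure_hierarchy")
}

#' Select the contextualisation scenario for a session
#'
#' Maps the session index onto the ranked hierarchy by linear interpolation:
#' session 1 gets the lowest-ranked situation, the final session the highest
#' mapped rank, and intermediate sessions are spread evenly, so anxiety rank
#' is monotonically non-decreasing across the programme.
#'
#' @param hierarchy an [rank_hierarchy()] result.
#' @param session_index 1-based session number.
#' @param config a [protocol_config()].
#' @return The selected `situation_id`.
#' @export
select_context_scenario <- function(hierarchy, session_index, config) {
  stopifnot(inherits(hierarchy, "exposure_hierarchy"))
  n_items <- nrow(hierarchy$items)
  ns <- config$n_sessions
  if (session_index < 1 || session_index > ns)
    stop("session_index out of range")
  rank <- if (ns == 1) 1L else
    round(1 + (session_index - 1) * (n_items - 1) / (ns - 1))
  hierarchy$items$situation_id[rank]
}

#' Build a full training programme of scheduled sessions
#'
#' Convenience wrapper: builds every session timeline and assigns stimuli.
#'
#' @inheritParams assign_stimuli
#' @param seed seed for the stimulus pool (overrides `pool$rng_seed`).
#' @return List of `event_timeline`s with stimuli assigned.
#' @export
build_programme <- function(config = protocol_config(),
                            pool = stimulus_pool(config$n_induction_phrases,
                                                 config$n_control_phrases),
                            seed = NULL) {
  if (!is.null(seed)) pool$rng_seed <- as.integer(seed)
  timelines <- lapply(seq_len(config$n_sessions),
                      function(s) build_session_timeline(config, s))
  assign_stimuli(config, pool, timelines)
}
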