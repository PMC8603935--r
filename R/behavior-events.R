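#' Construct a lick train
#'
#' A lick train holds the lick onset times (and optionally offsets) for one
#' session, in seconds from session start. Times must be sorted; duplicate
#' timestamps (simultaneous contacts, a lickometer artefact) are collapsed to
#' a single lick with a warning.
#'
#' @param onsets Numeric vector of lick onset times in seconds, strictly
#'   increasing after duplicate collapsing.
#' @param offsets Optional numeric vector of lick offsets, same length as
#'   `onsets`, with `offsets[i] >= onsets[i]`.
#' @param session_end Session length in seconds (default 3600, a 60-min
#'   session).
#' @return An object of class `lick_train` with elements `onsets`, `offsets`,
#'   `session_end`.
#' @examples
#' lt <- lick_train(c(0.1, 0.25, 0.4, 2.0))
#' length(lt$onsets)
#' @export
lick_train <- function(onsets, offsets = NULL, session_end = 3600) {
  onsets <- as.numeric(onsets)
  if (anyNA(onsets)) stop("lick onsets must not contain NA", call. = FALSE)
  if (is.unsorted(onsets)) {
    stop("lick onsets must be sorted in increasing order", call. = FALSE)
  }
  if (length(onsets) && (onsets[1] < 0 || onsets[length(onsets)] > session_end)) {
    stop("lick onsets must lie within [0, session_end]", call. = FALSE)
  }
  dup <- duplicated(onsets)
  if (any(dup)) {
    warning(sum(dup), " duplicate lick timestamp(s) collapsed", call. = FALSE)
    if (!is.null(offsets)) offsets <- offsets[!dup]
    onsets <- onsets[!dup]
  }
  if (!is.null(offsets)) {
    offsets <- as.numeric(offsets)
    if (length(offsets) != length(onsets)) {
      stop("offsets must have the same length as onsets", call. = FALSE)
    }
    if (any(offsets < onsets)) {
      stop("each offset must be >= its onset", call. = FALSE)
    }
  }
  structure(
    list(onsets = onsets, offsets = offsets, session_end = session_end),
    class = "lick_train"
  )
}

#' @export
print.lick_train <- function(x, ...) {
  cat("<lick_train> ", length(x$onsets), " licks over ", x$session_end,
      " s\n", sep = "")
  invisible(x)
}

#' Trigger-rule parameters
#'
#' Parameters of the closed-loop distractor trigger: a distractor is delivered
#' when the rat makes `burst_min_licks` consecutive licks within `burst_window`
#' seconds, provided licking had paused for more than `eligibility_pause`
#' seconds since the previous distractor (or since the previous burst).
#' A trial is classed as distracted when the post-distractor pause exceeds
#' `distraction_threshold`.
#'
#' @param burst_min_licks Minimum licks in the triggering run (default 3).
#' @param burst_window Maximum span, in s, of the triggering run (default 1).
#' @param eligibility_pause Pause, in s, that must precede a burst (and re-arm
#'   the trigger after a delivery); strict `>` (default 1).
#' @param distraction_threshold Post-event pause, in s, above which a trial is
#'   distracted; strict `>` (default 1).
#' @return An object of class `trigger_params`.
#' @export
trigger_params <- function(burst_min_licks = 3, burst_window = 1,
                           eligibility_pause = 1, distraction_threshold = 1) {
  if (burst_min_licks < 2) stop("burst_min_licks must be >= 2", call. = FALSE)
  vals <- c(burst_min_licks, burst_window, eligibility_pause,
            distraction_threshold)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all trigger parameters must be strictly positive", call. = FALSE)
  }
  structure(
    list(burst_min_licks = as.integer(burst_min_licks),
         burst_window = burst_window,
         eligibility_pause = eligibility_pause,
         distraction_threshold = distraction_threshold),
    class = "trigger_params"
  )
}

#' Closed vocabulary of distractor stimulus labels
#'
#' The delivered stimuli are a cue light, a flashing cue light, a tone, a
#' burst of white noise, or visual-by-auditory combinations of these.
#'
#' @return Character vector of valid stimulus labels.
#' @export
distractor_labels <- function() {
  c("light", "flashing_light", "tone", "white_noise",
    "light_tone", "light_white_noise",
    "flashing_light_tone", "flashing_light_white_noise")
}

# Maximal bursts of a lick train: runs whose every inter-lick interval is
# <= eligibility_pause. Returns start/end lick indices.
lick_bursts <- function(onsets, eligibility_pause) {
  n <- length(onsets)
  if (n == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  breaks <- which(diff(onsets) > eligibility_pause)
  start <- c(1L, breaks + 1L)
  end <- c(breaks, n)
  data.frame(start = start, end = end)
}

#' Detect distractor-trigger events in a lick train
#'
#' Applies the closed-loop trigger rule offline: a burst is a maximal run of
#' licks whose every inter-lick interval is at most `eligibility_pause`
#' (each such run is necessarily preceded by a pause longer than that, or by
#' session start). Within a burst the trigger fires at the first lick `j`
#' (counting from the burst's first lick) with `j >= burst_min_licks` and
#' `L_j - L_{j - burst_min_licks + 1} <= burst_window`; after a delivery no
#' further trigger can fire until an inter-lick interval exceeds
#' `eligibility_pause`, i.e. at most one trigger per burst. With the defaults
#' this fires on 3 consecutive licks within 1 s, and the recorded
#' `burst_position` falls in the 3-5 range whenever earlier triples were too
#' slow. Running this on a session recorded *without* distractors yields the
#' modelled (virtual) distractor times used as a behavioural null.
#'
#' @param licks A [lick_train()].
#' @param params A [trigger_params()].
#' @return A data.frame with columns `time` (trigger lick onset, s),
#'   `burst_position` (which lick of its burst fired), and `lick_index`
#'   (index into `licks$onsets`).
#' @examples
#' detect_trigger_events(lick_train(c(0, 0.2, 0.4, 0.6, 3)), trigger_params())
#' @export
detect_trigger_events <- function(licks, params = trigger_params()) {
  stopifnot(inherits(licks, "lick_train"), inherits(params, "trigger_params"))
  t <- licks$onsets
  k <- params$burst_min_licks
  out_time <- numeric(0)
  out_pos <- integer(0)
  out_idx <- integer(0)
  b <- lick_bursts(t, params$eligibility_pause)
  for (r in seq_len(nrow(b))) {
    s <- b$start[r]; e <- b$end[r]
    len <- e - s + 1L
    if (len < k) next
    for (j in k:len) {
      i <- s + j - 1L
      if (t[i] - t[i - k + 1L] <= params$burst_window) {
        out_time <- c(out_time, t[i])
        out_pos <- c(out_pos, j)
        out_idx <- c(out_idx, i)
        break  # re-arming needs an ILI > eligibility_pause: next burst
      }
    }
  }
  data.frame(time = out_time, burst_position = out_pos, lick_index = out_idx)
}

#' Classify a trial as distracted from the post-event pause
#'
#' The post-distractor pause is the time from the event to the next lick; the
#' trial is distracted when the pause exceeds `threshold` (strict `>`). When
#' no lick follows the event the pause is right-censored at session end and
#' the trial counts as distracted.
#'
#' @param licks A [lick_train()].
#' @param event_time Event time in seconds.
#' @param threshold Distraction threshold in seconds (default 1).
#' @return A list with `post_pause`, `distracted`, `censored`.
#' @export
classify_distraction <- function(licks, event_time, threshold = 1) {
  stopifnot(inherits(licks, "lick_train"))
  if (event_time > licks$session_end || event_time < 0) {
    stop("event_time outside session", call. = FALSE)
  }
  nxt <- licks$onsets[licks$onsets > event_time]
  if (length(nxt) == 0) {
    pause <- licks$session_end - event_time
    return(list(post_pause = pause, distracted = TRUE, censored = TRUE))
  }
  pause <- nxt[1] - event_time
  list(post_pause = pause, distracted = pause > threshold, censored = FALSE)
}

#' Pre-distractor pause for a triggering burst
#'
#' The pre-distractor pause runs from the last lick before the triggering
#' burst to the burst's first lick. When the burst is the session's first
#' licking, the pause is left-censored at the burst start time.
#'
#' @param licks A [lick_train()].
#' @param trigger_lick_index Index (into `licks$onsets`) of the lick that fired
#'   the trigger, as returned by [detect_trigger_events()].
#' @param params A [trigger_params()].
#' @return A list with `pre_pause` and `censored`.
#' @export
pre_distractor_pause <- function(licks, trigger_lick_index,
                                 params = trigger_params()) {
  stopifnot(inherits(licks, "lick_train"))
  b <- lick_bursts(licks$onsets, params$eligibility_pause)
  row <- which(b$start <= trigger_lick_index & b$end >= trigger_lick_index)
  if (length(row) != 1) stop("trigger index not inside any burst", call. = FALSE)
  s <- b$start[row]
  if (s == 1L) {
    list(pre_pause = licks$onsets[1], censored = TRUE)
  } else {
    list(pre_pause = licks$onsets[s] - licks$onsets[s - 1L], censored = FALSE)
  }
}

#' Build trials from a lick train and an event list
#'
#' Combines each distractor event (real or modelled) with its post- and
#' pre-event pauses, the distracted classification, and the position of the
#' trigger lick within its burst. Events supplied externally that do not land
#' on a detected trigger lick keep `burst_position = NA` and a censored
#' pre-pause.
#'
#' @param licks A [lick_train()].
#' @param events A data.frame with column `time` and optionally
#'   `stimulus_label` and `modelled`, sorted by time.
#' @param params A [trigger_params()].
#' @return A data.frame of class `distraction_trials`, one row per event:
#'   `time`, `stimulus_label`, `modelled`, `post_pause`, `distracted`,
#'   `censored_post`, `pre_pause`, `censored_pre`, `burst_position`.
#' @export
build_trials <- function(licks, events, params = trigger_params()) {
  stopifnot(inherits(licks, "lick_train"))
  if (is.numeric(events)) events <- data.frame(time = events)
  if (nrow(events) == 0) {
    out <- data.frame(time = numeric(0), stimulus_label = character(0),
                      modelled = logical(0), post_pause = numeric(0),
                      distracted = logical(0), censored_post = logical(0),
                      pre_pause = numeric(0), censored_pre = logical(0),
                      burst_position = integer(0))
    class(out) <- c("distraction_trials", "data.frame")
    return(out)
  }
  if (is.unsorted(events$time)) stop("events must be sorted by time", call. = FALSE)
  trig <- detect_trigger_events(licks, params)
  lab <- if ("stimulus_label" %in% names(events)) {
    as.character(events$stimulus_label)
  } else rep(NA_character_, nrow(events))
  mod <- if ("modelled" %in% names(events)) {
    as.logical(events$modelled)
  } else rep(FALSE, nrow(events))
  n <- nrow(events)
  post_pause <- pre_pause <- numeric(n)
  distracted <- cens_post <- cens_pre <- logical(n)
  burst_pos <- integer(n)
  for (i in seq_len(n)) {
    cl <- classify_distraction(licks, events$time[i],
                               params$distraction_threshold)
    post_pause[i] <- cl$post_pause
    distracted[i] <- cl$distracted
    cens_post[i] <- cl$censored
    m <- which(abs(trig$time - events$time[i]) < 1e-9)
    if (length(m) == 1) {
      burst_pos[i] <- trig$burst_position[m]
      pp <- pre_distractor_pause(licks, trig$lick_index[m], params)
      pre_pause[i] <- pp$pre_pause
      cens_pre[i] <- pp$censored
    } else {
      burst_pos[i] <- NA_integer_
      pre_pause[i] <- NA_real_
      cens_pre[i] <- TRUE
    }
  }
  if (anyNA(burst_pos)) {
    warning(sum(is.na(burst_pos)),
            " event(s) had no identifiable triggering burst", call. = FALSE)
  }
  out <- data.frame(time = events$time, stimulus_label = lab, modelled = mod,
                    post_pause = post_pause, distracted = distracted,
                    censored_post = cens_post, pre_pause = pre_pause,
                    censored_pre = cens_pre, burst_position = burst_pos)
  class(out) <- c("distraction_trials", "data.frame")
  out
}

#' Probability of distraction
#'
#' Proportion of trials classified as distracted. Censored post-pauses are
#' included (a rat that never licks again after an event was certainly
#' distracted).
#'
#' @param trials A trial data.frame from [build_trials()].
#' @return Proportion in \[0, 1\].
#' @export
distraction_probability <- function(trials) {
  if (nrow(trials) == 0) {
    stop("distraction probability undefined for an empty trial list",
         call. = FALSE)
  }
  mean(trials$distracted)
}

#' Peri-event lick rate matrix
#'
#' Bins licks into 1-s half-open bins `[t, t + bin)` around each event and
#' converts counts to rates. Events whose window does not fit inside the
#' session are dropped with a warning.
#'
#' @param licks A [lick_train()].
#' @param event_times Numeric vector of event times (s).
#' @param window Two-element window around the event, default `c(-5, 15)` s.
#' @param bin Bin width in s (default 1).
#' @return Matrix `trials x bins` of lick rates (licks/s), with `bin_start`
#'   (relative to the event) in the column attribute `bin_start`.
#' @export
peri_event_lick_rate <- function(licks, event_times, window = c(-5, 15),
                                 bin = 1) {
  stopifnot(inherits(licks, "lick_train"), length(window) == 2, bin > 0)
  edges <- seq(window[1], window[2], by = bin)
  nb <- length(edges) - 1L
  keep <- event_times + window[1] >= 0 &
    event_times + window[2] <= licks$session_end
  if (any(!keep)) {
    warning(sum(!keep), " event(s) dropped: peri-event window exceeds session",
            call. = FALSE)
  }
  ev <- event_times[keep]
  out <- matrix(0, nrow = length(ev), ncol = nb)
  for (i in seq_along(ev)) {
    rel <- licks$onsets - ev[i]
    rel <- rel[rel >= window[1] & rel < window[2]]
    out[i, ] <- tabulate(pmin(nb, floor((rel - window[1]) / bin) + 1L),
                         nbins = nb) / bin
  }
  attr(out, "bin_start") <- edges[-length(edges)]
  out
}

#' Split trials into chronological terciles
#'
#' Trials are split by session-time order into three contiguous groups; when
#' the count is not divisible by 3 the earlier groups take the extra trials.
#' Used to assess within-session habituation.
#'
#' @param trials A trial data.frame (rows in chronological order).
#' @return A list of three trial data.frames.
#' @export
tercile_groups <- function(trials) {
  n <- nrow(trials)
  if (n < 3) stop("need at least 3 trials to form terciles", call. = FALSE)
  base <- n %/% 3L
  r <- n %% 3L
  sizes <- base + as.integer(seq_len(3) <= r)
  idx <- split(seq_len(n), rep(1:3, times = sizes))
  lapply(idx, function(i) trials[i, , drop = FALSE])
}

#' Empirical CDF of pause durations
#'
#' Standard empirical cumulative distribution of post- (or pre-) event pause
#' durations; censored pauses enter at their censored value.
#'
#' @param pauses Numeric vector of pause durations (s).
#' @return A function of class `ecdf` (see [stats::ecdf()]).
#' @export
pause_ecdf <- function(pauses) {
  if (length(pauses) == 0) stop("no pauses supplied", call. = FALSE)
  stats::ecdf(pauses)
}
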