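#' Configuration for the synthetic session generator
#'
#' Defines the study conditions emulated by the generator: burst-structured
#' licking (lognormal intra-burst inter-lick intervals around 0.14 s, i.e.
#' ~7 Hz licking; geometric burst lengths; lognormal inter-burst pauses with
#' a median of a few seconds), a closed-loop distractor-delivery policy
#' identical to [detect_trigger_events()], a Bernoulli distraction response
#' (with probability `p_distract` a delivered distractor switches the next
#' pause to a long, truncated-lognormal "distracted" pause), and two-channel
#' photometry: a double-exponential bleach and transient artefacts shared
#' across channels, plus calcium-channel-only event-locked GCaMP6s-like
#' transients whose amplitude depends on the trial's distracted gate.
#'
#' The defaults are calibrated to the study conditions: a burst-length
#' geometric parameter of 0.035 makes the spontaneous chance that a trigger
#' lands on the final lick of a burst (and is hence followed by a long pause)
#' about 0.035, and `p_distract = 0.465` then yields a measured distraction
#' probability of about 0.484 on a first distraction day; habituation is
#' emulated by lowering `p_distract` (0.21 gives ~0.238 measured) while the
#' neural transient amplitudes are left unchanged.
#'
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param session_length Session length in s (default 3600).
#' @param deliver_distractors Deliver stimuli when the trigger fires? `FALSE`
#'   emulates a lick-training day (the behavioural null for modelled
#'   distractors).
#' @param intra_burst_ili `c(meanlog, sdlog)` of the within-burst inter-lick
#'   interval (s).
#' @param burst_length_p Geometric parameter; burst length = 1 + Geom(p).
#' @param inter_burst_pause `c(meanlog, sdlog)` of the between-burst pause (s).
#' @param p_distract Probability a delivered distractor gates a long pause.
#' @param distracted_pause `c(meanlog, sdlog)` of the distracted pause (s),
#'   truncated below at the distraction threshold.
#' @param trigger A [trigger_params()].
#' @param photometry Named list of photometry parameters; see
#'   [photometry_defaults()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         session_length = 3600,
                         deliver_distractors = TRUE,
                         intra_burst_ili = c(meanlog = log(0.14), sdlog = 0.2),
                         burst_length_p = 0.035,
                         inter_burst_pause = c(meanlog = log(4), sdlog = 0.6),
                         p_distract = 0.465,
                         distracted_pause = c(meanlog = log(5), sdlog = 0.8),
                         trigger = trigger_params(),
                         photometry = photometry_defaults()) {
  cfg <- list(seed = as.integer(seed), session_length = session_length,
              deliver_distractors = deliver_distractors,
              intra_burst_ili = intra_burst_ili,
              burst_length_p = burst_length_p,
              inter_burst_pause = inter_burst_pause,
              p_distract = p_distract,
              distracted_pause = distracted_pause,
              trigger = trigger, photometry = photometry)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' Default photometry-simulation parameters
#'
#' Raw-unit (arbitrary fluorescence) parameters of the simulated acquisition:
#' isosbestic operating level plus a double-exponential bleach; shared
#' exponential-decay movement artefacts; per-channel Gaussian noise,
#' band-limited at `lowpass_hz` to emulate the acquisition lowpass; and a
#' two-exponential GCaMP6s-like transient kernel (rise 0.2 s, decay 1.5 s)
#' added to the calcium channel at each delivered distractor, scaled by
#' `amplitude_distracted` or `amplitude_not_distracted` (peak dF/F units)
#' according to the trial's gate.
#'
#' @param fs Sampling rate in Hz (default 100; desk-scale stand-in for the
#'   kHz acquisition rate).
#' @return Named list of parameters.
#' @export
photometry_defaults <- function(fs = 100) {
  list(fs = fs,
       iso_level = 200, ca_slope = 1.8, ca_intercept = 40,
       bleach_amp = c(30, 60), bleach_tau = c(120, 2400),
       artifact_rate = 0.01, artifact_amp = -15, artifact_tau = 0.3,
       noise_sd_ca = 2.0, noise_sd_iso = 2.0, lowpass_hz = 3,
       transient_rise_tau = 0.2, transient_decay_tau = 1.5,
       amplitude_distracted = 0.012, amplitude_not_distracted = 0.005)
}

validate_synth_config <- function(cfg) {
  if (cfg$p_distract < 0 || cfg$p_distract > 1) {
    stop("p_distract must lie in [0, 1]", call. = FALSE)
  }
  if (exp(cfg$intra_burst_ili[["meanlog"]]) > cfg$trigger$eligibility_pause) {
    stop("degenerate config: median intra-burst ILI exceeds the eligibility ",
         "pause, bursts cannot form", call. = FALSE)
  }
  if (cfg$burst_length_p <= 0 || cfg$burst_length_p >= 1) {
    stop("burst_length_p must lie in (0, 1)", call. = FALSE)
  }
  ph <- cfg$photometry
  if (ph$fs < 5 / ph$transient_decay_tau) {
    stop("photometry fs too low to resolve the transient kernel",
         call. = FALSE)
  }
  invisible(cfg)
}

# lognormal truncated below at `lo` via inverse-CDF sampling
rlnorm_trunc <- function(n, meanlog, sdlog, lo) {
  q <- stats::plnorm(lo, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, q, 1), meanlog, sdlog)
}

#' Generate a closed-loop synthetic licking session
#'
#' Simulates licking burst by burst while running the trigger detector
#' online, so the delivered distractor times are exactly what
#' [detect_trigger_events()] recovers offline from the emitted lick train.
#' When a distractor is delivered, a Bernoulli gate (probability
#' `p_distract`) decides whether the burst is interrupted by a long
#' "distracted" pause; otherwise the burst continues under the baseline
#' model (and can still, by chance, end in a long pause — the spontaneous
#' long-pause rate that modelled distractors measure).
#'
#' @param config A [synth_config()].
#' @return A list with `licks` (a [lick_train()]), `events` (data.frame
#'   `time`, `stimulus_label`, `modelled`), and `manifest` (ground truth:
#'   per-trial delivered time, label, the gate's distracted flag, injected
#'   transient amplitude, and the generator config).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  tp <- config$trigger
  k <- tp$burst_min_licks
  ili_ml <- config$intra_burst_ili[["meanlog"]]
  ili_sl <- config$intra_burst_ili[["sdlog"]]
  pause_ml <- config$inter_burst_pause[["meanlog"]]
  pause_sl <- config$inter_burst_pause[["sdlog"]]
  dp_ml <- config$distracted_pause[["meanlog"]]
  dp_sl <- config$distracted_pause[["sdlog"]]

  licks <- numeric(0)
  ev_time <- numeric(0); ev_label <- character(0); ev_gate <- logical(0)
  # online detector state
  run_len <- 0L; fired <- FALSE; last_lick <- -Inf
  t <- stats::rlnorm(1, pause_ml, pause_sl)  # first burst after an initial pause
  while (t <= config$session_length) {
    planned <- 1L + stats::rgeom(1, config$burst_length_p)
    emitted <- 0L
    interrupted <- FALSE
    while (emitted < planned && t <= config$session_length) {
      # emit lick at t
      gap <- t - last_lick
      if (gap > tp$eligibility_pause) { run_len <- 1L; fired <- FALSE }
      else run_len <- run_len + 1L
      licks <- c(licks, t)
      last_lick <- t
      emitted <- emitted + 1L
      i <- length(licks)
      if (!fired && run_len >= k &&
          licks[i] - licks[i - k + 1L] <= tp$burst_window) {
        fired <- TRUE
        if (config$deliver_distractors) {
          ev_time <- c(ev_time, t)
          ev_label <- c(ev_label, sample(distractor_labels(), 1))
          gate <- stats::runif(1) < config$p_distract
          ev_gate <- c(ev_gate, gate)
          if (gate) { interrupted <- TRUE; break }
        }
      }
      if (emitted < planned) t <- t + stats::rlnorm(1, ili_ml, ili_sl)
    }
    pause <- if (interrupted) {
      rlnorm_trunc(1, dp_ml, dp_sl, tp$distraction_threshold)
    } else {
      stats::rlnorm(1, pause_ml, pause_sl)
    }
    t <- last_lick + pause
  }
  licks <- licks[licks <= config$session_length]
  ph <- config$photometry
  manifest <- list(
    trials = data.frame(
      time = ev_time, stimulus_label = ev_label, gate_distracted = ev_gate,
      amplitude = ifelse(ev_gate, ph$amplitude_distracted,
                         ph$amplitude_not_distracted)),
    config = config)
  list(
    licks = lick_train(licks, session_end = config$session_length),
    events = data.frame(time = ev_time, stimulus_label = ev_label,
                        modelled = rep(FALSE, length(ev_time))),
    manifest = manifest
  )
}

# peak-normalised two-exponential transient kernel sampled at fs
transient_kernel <- function(fs, rise_tau, decay_tau, length_s = 10) {
  tt <- seq(0, length_s, by = 1 / fs)
  k <- exp(-tt / decay_tau) - exp(-tt / rise_tau)
  k / max(k)
}

#' Generate a synthetic two-channel photometry session
#'
#' Builds the isosbestic channel as operating level + double-exponential
#' bleach + shared artefacts + band-limited noise, and the calcium channel as
#' an affine function of the same shared structure plus event-locked
#' transients (amplitude per trial from the ground-truth manifest) and
#' independent noise. Both channels are strictly positive under sensible
#' parameters; the shared structure is exactly what
#' [correct_isosbestic()] is designed to remove.
#'
#' @param events Event data.frame (times used only for reference; the
#'   transients are placed at the manifest's trial times).
#' @param manifest Ground-truth manifest from [generate_session()].
#' @param config A [synth_config()].
#' @return A [photometry_session()]. The per-trial injected amplitudes are in
#'   `manifest$trials$amplitude`.
#' @export
generate_photometry <- function(events, manifest, config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  ph <- config$photometry
  set.seed(config$seed + 1L)
  n <- as.integer(round(config$session_length * ph$fs))
  tt <- (seq_len(n) - 1) / ph$fs
  bleach <- ph$bleach_amp[1] * exp(-tt / ph$bleach_tau[1]) +
    ph$bleach_amp[2] * exp(-tt / ph$bleach_tau[2])
  shared <- bleach
  n_art <- stats::rpois(1, ph$artifact_rate * config$session_length)
  art_times <- sort(stats::runif(n_art, 0, config$session_length))
  akern <- ph$artifact_amp *
    exp(-seq(0, 5 * ph$artifact_tau, by = 1 / ph$fs) / ph$artifact_tau)
  for (at in art_times) {
    i0 <- as.integer(floor(at * ph$fs)) + 1L
    idx <- i0:min(n, i0 + length(akern) - 1L)
    shared[idx] <- shared[idx] + akern[seq_along(idx)]
  }
  ca_ref <- ph$ca_intercept + ph$ca_slope * (ph$iso_level + shared)
  trans <- numeric(n)
  trials <- manifest$trials
  if (nrow(trials) > 0) {
    kern <- transient_kernel(ph$fs, ph$transient_rise_tau,
                             ph$transient_decay_tau)
    level0 <- ph$ca_intercept + ph$ca_slope * ph$iso_level
    for (j in seq_len(nrow(trials))) {
      i0 <- as.integer(floor(trials$time[j] * ph$fs)) + 1L
      if (i0 > n) next
      idx <- i0:min(n, i0 + length(kern) - 1L)
      trans[idx] <- trans[idx] + trials$amplitude[j] * level0 *
        kern[seq_along(idx)]
    }
  }
  noise_iso <- stats::rnorm(n, 0, ph$noise_sd_iso)
  noise_ca <- stats::rnorm(n, 0, ph$noise_sd_ca)
  if (!is.null(ph$lowpass_hz) && ph$lowpass_hz > 0 &&
      ph$fs > 2 * ph$lowpass_hz) {
    bf <- signal::butter(2, ph$lowpass_hz / (ph$fs / 2), type = "low")
    noise_iso <- signal::filtfilt(bf, noise_iso)
    noise_ca <- signal::filtfilt(bf, noise_ca)
  }
  iso <- ph$iso_level + shared + noise_iso
  ca <- ca_ref + trans + noise_ca
  if (any(iso <= 0) || any(ca <= 0)) {
    stop("simulated channels are not strictly positive; adjust levels",
         call. = FALSE)
  }
  photometry_session(ca, iso, ph$fs, t0_offset = 0)
}

#' Write a deterministic fixture study to disk
#'
#' Generates a small study — `n_rats` rats, each with a lick-training day
#' (no distractors; the modelled-distractor null), a first distraction day
#' and a habituation day with reduced `p_distract` — and writes the
#' behavioural CSVs, photometry CSVs and ground-truth JSON manifests, plus a
#' `study.json` index consumed by [load_study()].
#'
#' @param out_dir Output directory (created if absent).
#' @param n_rats Number of simulated rats (default 6).
#' @param seed Base seed; per-session seeds are derived from it.
#' @param session_length Session length in s (default 3600).
#' @param fs Photometry sampling rate in Hz (default 100).
#' @param p_distract_day1 Gate probability on the first distraction day
#'   (default 0.465).
#' @param p_distract_day2 Gate probability on the habituation day
#'   (default 0.21).
#' @param photometry Generate and write photometry channels too? (default
#'   TRUE)
#' @return Invisibly, the path of the written `study.json` index.
#' @export
fixture_suite <- function(out_dir, n_rats = 6, seed = 20201,
                          session_length = 3600, fs = 100,
                          p_distract_day1 = 0.465, p_distract_day2 = 0.21,
                          photometry = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  days <- c("lick", "distraction", "habituation")
  p_by_day <- c(lick = 0, distraction = p_distract_day1,
                habituation = p_distract_day2)
  index <- list()
  for (r in seq_len(n_rats)) {
    rat <- sprintf("rat%02d", r)
    for (d in seq_along(days)) {
      day <- days[d]
      cfg <- synth_config(
        seed = seed + 37L * r + d,
        session_length = session_length,
        deliver_distractors = day != "lick",
        p_distract = p_by_day[[day]],
        photometry = photometry_defaults(fs = fs))
      ses <- generate_session(cfg)
      base <- file.path(out_dir, paste0(rat, "_", day))
      write_behavior_csv(paste0(base, "_behavior.csv"), rat, day,
                         ses$licks, ses$events)
      files <- list(behavior = basename(paste0(base, "_behavior.csv")))
      if (photometry) {
        pho <- generate_photometry(ses$events, ses$manifest, cfg)
        write_photometry_csv(paste0(base, "_photometry.csv"), pho)
        files$photometry <- basename(paste0(base, "_photometry.csv"))
      }
      man <- ses$manifest
      man$config <- unclass_config(cfg)
      jsonlite::write_json(man, paste0(base, "_manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      files$manifest <- basename(paste0(base, "_manifest.json"))
      index[[length(index) + 1L]] <- c(list(rat_id = rat, day = day), files)
    }
  }
  idx_path <- file.path(out_dir, "study.json")
  jsonlite::write_json(list(sessions = index), idx_path, auto_unbox = TRUE)
  invisible(idx_path)
}

# JSON-safe view of a synth_config (named vectors become objects)
unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$trigger <- unclass(out$trigger)
  out
}
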