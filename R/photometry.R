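#' Construct a photometry session
#'
#' Holds one session's paired demodulated signals: the calcium-modulated
#' 470 nm channel and the calcium-independent isosbestic 405 nm channel,
#' sampled at `fs` Hz. `t0_offset` places sample 1 on the behavioural clock,
#' so sample `i` occurs at `t0_offset + (i - 1) / fs` seconds.
#'
#' @param ca Numeric vector, calcium-modulated signal.
#' @param iso Numeric vector, isosbestic signal, same length.
#' @param fs Sampling rate in Hz.
#' @param t0_offset Behavioural-clock time of the first sample (s), default 0.
#' @return An object of class `photometry_session`.
#' @export
photometry_session <- function(ca, iso, fs, t0_offset = 0) {
  ca <- as.numeric(ca); iso <- as.numeric(iso)
  if (length(ca) != length(iso)) {
    stop("ca and iso channels must have the same length", call. = FALSE)
  }
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (!all(is.finite(ca)) || !all(is.finite(iso))) {
    stop("photometry samples must be finite", call. = FALSE)
  }
  structure(list(ca = ca, iso = iso, fs = fs, t0_offset = t0_offset),
            class = "photometry_session")
}

#' @export
print.photometry_session <- function(x, ...) {
  cat("<photometry_session> ", length(x$ca), " samples @ ", x$fs, " Hz (",
      round(length(x$ca) / x$fs, 1), " s)\n", sep = "")
  invisible(x)
}

#' Correct the calcium channel with the isosbestic reference
#'
#' Removes bleaching and shared motion artefacts by ordinary least-squares
#' regression of the calcium channel onto the isosbestic channel over the
#' whole session; the corrected signal is
#' `dff = (ca - fitted) / fitted`, a unitless fractional change relative to
#' the fitted reference. Any component of the calcium channel that is an
#' affine function of the isosbestic channel is annihilated exactly.
#'
#' @param session A [photometry_session()].
#' @return A list of class `corrected_trace` with `dff`, `fs`, `t0_offset`,
#'   `fit_slope`, `fit_intercept`.
#' @export
correct_isosbestic <- function(session) {
  stopifnot(inherits(session, "photometry_session"))
  if (stats::sd(session$iso) == 0) {
    stop("isosbestic channel is constant; degenerate reference fit",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, session$iso), session$ca)
  fitted <- session$ca - fit$residuals
  if (any(fitted <= 0)) {
    stop("fitted reference crosses zero; re-baseline the raw signals before ",
         "correction", call. = FALSE)
  }
  structure(
    list(dff = fit$residuals / fitted,
         fs = session$fs,
         t0_offset = session$t0_offset,
         fit_slope = unname(fit$coefficients[2]),
         fit_intercept = unname(fit$coefficients[1])),
    class = "corrected_trace"
  )
}

#' @export
print.corrected_trace <- function(x, ...) {
  cat("<corrected_trace> ", length(x$dff), " samples @ ", x$fs,
      " Hz; fit slope ", signif(x$fit_slope, 4), "\n", sep = "")
  invisible(x)
}

#' Extract event-aligned snips
#'
#' Cuts a window (default 5 s before to 15 s after) around each event from a
#' corrected trace and decimates it to `target_fs` by block averaging (each
#' output sample is the mean of `fs / target_fs` consecutive raw samples).
#' Events whose window does not fit inside the recording are dropped with a
#' warning.
#'
#' @param trace A `corrected_trace` from [correct_isosbestic()], or any list
#'   with elements `dff`, `fs`, `t0_offset`.
#' @param event_times Event times on the behavioural clock (s).
#' @param window Window around the event, default `c(-5, 15)` s.
#' @param target_fs Output sampling rate in Hz (default 10); `fs / target_fs`
#'   must be a whole number and `target_fs <= fs`.
#' @return A list of class `snip_matrix`: `data` (trials x samples), `fs`
#'   (= target_fs), `window`, `normalized = FALSE`, `event_times` (retained),
#'   `dropped` (indices of dropped events).
#' @export
extract_snips <- function(trace, event_times, window = c(-5, 15),
                          target_fs = 10) {
  if (target_fs > trace$fs) {
    stop("target_fs must not exceed the recording rate", call. = FALSE)
  }
  block <- trace$fs / target_fs
  if (abs(block - round(block)) > 1e-8) {
    stop("fs must be an integer multiple of target_fs for block averaging",
         call. = FALSE)
  }
  block <- as.integer(round(block))
  n <- length(trace$dff)
  rec_start <- trace$t0_offset
  rec_end <- trace$t0_offset + n / trace$fs
  keep <- event_times + window[1] >= rec_start &
    event_times + window[2] <= rec_end
  if (any(!keep)) {
    warning(sum(!keep), " event(s) dropped: snip window exceeds recording",
            call. = FALSE)
  }
  ev <- event_times[keep]
  span <- window[2] - window[1]
  nraw <- as.integer(round(span * trace$fs))
  nout <- nraw %/% block
  data <- matrix(NA_real_, nrow = length(ev), ncol = nout)
  for (i in seq_along(ev)) {
    i0 <- as.integer(round((ev[i] + window[1] - trace$t0_offset) * trace$fs)) + 1L
    seg <- trace$dff[i0:(i0 + nraw - 1L)]
    data[i, ] <- colMeans(matrix(seg, nrow = block))
  }
  structure(
    list(data = data, fs = target_fs, window = window, normalized = FALSE,
         baseline_window = NULL, event_times = ev,
         dropped = which(!keep)),
    class = "snip_matrix"
  )
}

#' @export
print.snip_matrix <- function(x, ...) {
  cat("<snip_matrix> ", nrow(x$data), " trials x ", ncol(x$data),
      " samples @ ", x$fs, " Hz, window [", x$window[1], ", ", x$window[2],
      ") s", if (x$normalized) ", z-scored" else "", "\n", sep = "")
  invisible(x)
}

# sample indices of a snip-relative time interval [from, to)
snip_cols <- function(snips, from, to) {
  i0 <- as.integer(round((from - snips$window[1]) * snips$fs)) + 1L
  i1 <- as.integer(round((to - snips$window[1]) * snips$fs))
  i0:i1
}

#' Z-score snips to a pre-event baseline
#'
#' Normalises each trial's trace to its own baseline: subtract the mean and
#' divide by the SD of the samples in `baseline` (default the 5 s before the
#' event). Rows with zero baseline SD cannot be normalised and are dropped
#' with a warning.
#'
#' @param snips A `snip_matrix` from [extract_snips()].
#' @param baseline Baseline interval relative to the event, default `c(-5, 0)`.
#' @return A normalised `snip_matrix`.
#' @export
zscore_snips <- function(snips, baseline = c(-5, 0)) {
  stopifnot(inherits(snips, "snip_matrix"))
  if (baseline[1] < snips$window[1] || baseline[2] > snips$window[2]) {
    stop("baseline must lie within the snip window", call. = FALSE)
  }
  cols <- snip_cols(snips, baseline[1], baseline[2])
  bm <- rowMeans(snips$data[, cols, drop = FALSE])
  bs <- apply(snips$data[, cols, drop = FALSE], 1, stats::sd)
  bad <- bs == 0
  if (any(bad)) {
    warning(sum(bad), " trial(s) dropped: zero baseline SD", call. = FALSE)
  }
  out <- snips
  out$data <- (snips$data - bm) / bs
  out$data <- out$data[!bad, , drop = FALSE]
  out$event_times <- snips$event_times[!bad]
  out$normalized <- TRUE
  out$baseline_window <- baseline
  out
}

#' Average snips into 1-s time bins
#'
#' Per-trial mean of the trace within each half-open 1-s bin across the snip
#' window; with the default window this yields a trials x 20 matrix matching
#' the bin-wise ROC analyses.
#'
#' @param snips A `snip_matrix`.
#' @param bin Bin width in s (default 1).
#' @return Matrix `trials x bins` with attribute `bin_start` (bin left edges
#'   relative to the event).
#' @export
bin_snips <- function(snips, bin = 1) {
  stopifnot(inherits(snips, "snip_matrix"))
  per <- as.integer(round(bin * snips$fs))
  nb <- ncol(snips$data) %/% per
  out <- matrix(NA_real_, nrow = nrow(snips$data), ncol = nb)
  for (b in seq_len(nb)) {
    cols <- ((b - 1L) * per + 1L):(b * per)
    out[, b] <- rowMeans(snips$data[, cols, drop = FALSE])
  }
  attr(out, "bin_start") <- snips$window[1] + (seq_len(nb) - 1) * bin
  out
}

#' Default analysis epochs
#'
#' The main-text epochs: baseline −5 to −1 s, early post-event 1 to 4 s,
#' late post-event 5 to 15 s. The figure-caption variant (1–3 s and 4–15 s)
#' is available as `epoch_defs("caption")`.
#'
#' @param which `"main"` (default) or `"caption"`.
#' @return Named list of `c(from, to)` intervals (s, relative to the event).
#' @export
epoch_defs <- function(which = c("main", "caption")) {
  which <- match.arg(which)
  if (which == "main") {
    list(pre = c(-5, -1), early_post = c(1, 4), late_post = c(5, 15))
  } else {
    list(pre = c(-5, -1), early_post = c(1, 3), late_post = c(4, 15))
  }
}

#' Per-trial (and optionally per-subject) epoch means
#'
#' Averages each trial's snip within named, non-overlapping epochs. When
#' `rat_id` and `condition` are supplied the per-trial values are further
#' averaged into one row per rat, condition and epoch, the unit entering the
#' repeated-measures comparisons.
#'
#' @param snips A `snip_matrix`.
#' @param epochs Named list of `c(from, to)` intervals; default [epoch_defs()].
#' @param rat_id Optional per-trial subject ids.
#' @param condition Optional per-trial condition labels.
#' @return If no grouping: a data.frame `trial x epoch` of means (long
#'   format: `trial`, `epoch`, `value`). With grouping: `rat_id`, `condition`,
#'   `epoch`, `value` (mean over trials).
#' @export
epoch_means <- function(snips, epochs = epoch_defs(), rat_id = NULL,
                        condition = NULL) {
  stopifnot(inherits(snips, "snip_matrix"))
  iv <- do.call(rbind, epochs)
  if (any(iv[, 1] < snips$window[1]) || any(iv[, 2] > snips$window[2])) {
    stop("epochs must lie within the snip window", call. = FALSE)
  }
  ord <- order(iv[, 1])
  if (any(iv[ord, 1][-1] < iv[ord, 2][-length(epochs)])) {
    stop("epochs must not overlap", call. = FALSE)
  }
  vals <- lapply(names(epochs), function(nm) {
    cols <- snip_cols(snips, epochs[[nm]][1], epochs[[nm]][2])
    data.frame(trial = seq_len(nrow(snips$data)), epoch = nm,
               value = rowMeans(snips$data[, cols, drop = FALSE]))
  })
  long <- do.call(rbind, vals)
  long$epoch <- factor(long$epoch, levels = names(epochs))
  if (is.null(rat_id)) return(long)
  stopifnot(length(rat_id) == nrow(snips$data))
  if (is.null(condition)) condition <- rep("all", nrow(snips$data))
  long$rat_id <- rat_id[long$trial]
  long$condition <- condition[long$trial]
  agg <- stats::aggregate(value ~ rat_id + condition + epoch, data = long,
                          FUN = mean)
  agg[order(agg$rat_id, agg$condition, agg$epoch), ]
}

#' Whole-session RMS of the corrected signal
#'
#' Root-mean-square of the (non-z-scored) dF/F over the entire session, a
#' summary of overall signal fluctuation used to compare sessions.
#'
#' @param trace A `corrected_trace`.
#' @return A single non-negative number.
#' @export
session_rms <- function(trace) {
  if (length(trace$dff) == 0) stop("empty trace", call. = FALSE)
  sqrt(mean(trace$dff^2))
}
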