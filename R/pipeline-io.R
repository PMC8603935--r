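#' Write a behavioural events CSV
#'
#' Long-format session file with columns `rat_id`, `session_id`,
#' `event_type` (`lick_on`, `lick_off`, `distractor`), `time_s`,
#' `stimulus_label` (empty for licks) and `modelled` (0/1).
#'
#' @param path Output file path.
#' @param rat_id,session_id Identifiers written on every row.
#' @param licks A [lick_train()].
#' @param events Data.frame with `time` and optionally `stimulus_label`,
#'   `modelled`.
#' @return Invisibly, `path`.
#' @export
write_behavior_csv <- function(path, rat_id, session_id, licks,
                               events = NULL) {
  rows <- data.table::data.table(
    rat_id = rat_id, session_id = session_id, event_type = "lick_on",
    time_s = licks$onsets, stimulus_label = "", modelled = 0L)
  if (!is.null(licks$offsets)) {
    rows <- rbind(rows, data.table::data.table(
      rat_id = rat_id, session_id = session_id, event_type = "lick_off",
      time_s = licks$offsets, stimulus_label = "", modelled = 0L))
  }
  if (!is.null(events) && nrow(events) > 0) {
    lab <- if ("stimulus_label" %in% names(events)) {
      as.character(events$stimulus_label)
    } else ""
    mod <- if ("modelled" %in% names(events)) {
      as.integer(events$modelled)
    } else 0L
    rows <- rbind(rows, data.table::data.table(
      rat_id = rat_id, session_id = session_id, event_type = "distractor",
      time_s = events$time, stimulus_label = lab, modelled = mod))
  }
  data.table::setorder(rows, time_s)
  data.table::fwrite(rows, path)
  invisible(path)
}

#' Read a behavioural events CSV
#'
#' Parses and validates one session written by [write_behavior_csv()]; a lick
#' ordering violation is reported with the offending file and row.
#'
#' @param path File path.
#' @param session_end Session length in s (default 3600).
#' @return A list with `rat_id`, `session_id`, `licks` (a [lick_train()]) and
#'   `events` (data.frame `time`, `stimulus_label`, `modelled`).
#' @export
read_behavior_csv <- function(path, session_end = 3600) {
  d <- data.table::fread(path, colClasses = list(character = "stimulus_label"))
  need <- c("rat_id", "session_id", "event_type", "time_s")
  if (!all(need %in% names(d))) {
    stop("behaviour file ", path, " lacks required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  on_rows <- which(d$event_type == "lick_on")
  on_times <- d$time_s[on_rows]
  if (is.unsorted(on_times)) {
    bad <- on_rows[which(diff(on_times) < 0)[1] + 1L]
    stop("unsorted lick onsets in ", path, " at row ", bad, call. = FALSE)
  }
  ev <- d[d$event_type == "distractor", ]
  licks <- lick_train(on_times, session_end = max(session_end,
                                                  max(d$time_s)))
  list(rat_id = d$rat_id[1], session_id = d$session_id[1], licks = licks,
       events = data.frame(time = ev$time_s,
                           stimulus_label = ev$stimulus_label,
                           modelled = as.logical(ev$modelled)))
}

#' Write a photometry session to CSV
#'
#' Columns `time_s` (behavioural clock), `ca`, `iso`. The sampling rate and
#' clock offset are carried by the time column itself.
#'
#' @param path Output file path.
#' @param session A [photometry_session()].
#' @return Invisibly, `path`.
#' @export
write_photometry_csv <- function(path, session) {
  stopifnot(inherits(session, "photometry_session"))
  n <- length(session$ca)
  data.table::fwrite(data.table::data.table(
    time_s = session$t0_offset + (seq_len(n) - 1) / session$fs,
    ca = session$ca, iso = session$iso), path)
  invisible(path)
}

#' Read a photometry CSV
#'
#' Reconstructs a [photometry_session()] from a `time_s`, `ca`, `iso` file;
#' `fs` is inferred from the median sample interval and `t0_offset` from the
#' first time stamp.
#'
#' @param path File path.
#' @return A [photometry_session()].
#' @export
read_photometry_csv <- function(path) {
  d <- data.table::fread(path)
  need <- c("time_s", "ca", "iso")
  if (!all(need %in% names(d))) {
    stop("photometry file ", path, " lacks required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  dt <- stats::median(diff(d$time_s))
  photometry_session(d$ca, d$iso, fs = 1 / dt, t0_offset = d$time_s[1])
}

#' Load a study from disk
#'
#' Reads a `study.json` index (as written by [fixture_suite()]) or a
#' directory containing one, loads each session's behavioural and photometry
#' files, and runs integrity checks (lick ordering, matching channel
#' lengths).
#'
#' @param path Path to `study.json` or its directory.
#' @param session_end Session length in s (default 3600).
#' @return A list of class `distraction_study`: one element per session with
#'   `rat_id`, `day`, `licks`, `events`, `photometry` (or NULL), `manifest`
#'   (or NULL).
#' @export
load_study <- function(path, session_end = 3600) {
  if (dir.exists(path)) path <- file.path(path, "study.json")
  if (!file.exists(path)) stop("study index not found: ", path, call. = FALSE)
  idx <- jsonlite::read_json(path)
  base <- dirname(path)
  sessions <- lapply(idx$sessions, function(s) {
    beh <- read_behavior_csv(file.path(base, s$behavior), session_end)
    pho <- if (!is.null(s$photometry)) {
      read_photometry_csv(file.path(base, s$photometry))
    } else NULL
    man <- if (!is.null(s$manifest)) {
      jsonlite::read_json(file.path(base, s$manifest), simplifyVector = TRUE)
    } else NULL
    if (!is.null(pho) && length(pho$ca) != length(pho$iso)) {
      stop("channel length mismatch in ", s$photometry, call. = FALSE)
    }
    list(rat_id = s$rat_id, day = s$day, licks = beh$licks,
         events = beh$events, photometry = pho, manifest = man)
  })
  structure(sessions, class = "distraction_study")
}

#' @export
print.distraction_study <- function(x, ...) {
  cat("<distraction_study> ", length(x), " sessions, ",
      length(unique(vapply(x, `[[`, "", "rat_id"))), " rats\n", sep = "")
  invisible(x)
}

# trials for one session; lick-day sessions get modelled distractors from the
# offline trigger scan
session_trials <- function(ses, params) {
  if (nrow(ses$events) > 0) {
    ev <- ses$events
  } else {
    trig <- detect_trigger_events(ses$licks, params)
    ev <- data.frame(time = trig$time, stimulus_label = NA_character_,
                     modelled = rep(TRUE, nrow(trig)))
  }
  tr <- build_trials(ses$licks, ev, params)
  if (nrow(tr) > 0) {
    tr$rat_id <- ses$rat_id
    tr$day <- ses$day
    # was another distractor present within the 5 s baseline?
    tr$prior_event_in_baseline <- vapply(seq_len(nrow(tr)), function(i) {
      any(ev$time >= tr$time[i] - 5 & ev$time < tr$time[i])
    }, logical(1))
  }
  tr
}

# per-session photometry products: z-scored and raw binned matrices plus
# trial metadata aligned to retained snips
session_snips <- function(ses, trials, window = c(-5, 15), target_fs = 10,
                          baseline = c(-5, 0)) {
  if (is.null(ses$photometry)) return(NULL)
  trace <- correct_isosbestic(ses$photometry)
  snips <- suppressWarnings(
    extract_snips(trace, trials$time, window, target_fs))
  zs <- suppressWarnings(zscore_snips(snips, baseline))
  meta_raw <- trials[match(snips$event_times, trials$time), , drop = FALSE]
  meta_z <- trials[match(zs$event_times, trials$time), , drop = FALSE]
  list(trace = trace,
       z = zs, z_binned = bin_snips(zs), z_meta = meta_z,
       raw = snips, raw_binned = bin_snips(snips), raw_meta = meta_raw)
}

# rats x epochs x conditions array from per-rat epoch mean tables
epoch_array <- function(df, rats, epochs, conditions) {
  arr <- array(NA_real_, dim = c(length(rats), length(epochs),
                                 length(conditions)),
               dimnames = list(rats, epochs, conditions))
  for (i in seq_len(nrow(df))) {
    arr[df$rat_id[i], as.character(df$epoch[i]),
        as.character(df$condition[i])] <- df$value[i]
  }
  arr
}

#' Run the full distraction analysis
#'
#' Executes the complete pipeline on a loaded study: modelled-distractor
#' detection on lick-training days, trial building and distraction
#' classification on distractor days, day-level probability and
#' log-pause contrasts, pooled bin-wise lick-rate ROC (distracted vs not),
#' photometry correction / snip extraction / z-scoring / binning followed by
#' the ROC panels (modelled vs first distraction day; distracted vs not;
#' first vs second distraction day overall and split by trial class),
#' epoch repeated-measures ANOVAs, and the supplementary analyses (terciles,
#' stimulus-type contrast, non-z-scored epochs, session RMS and baseline
#' t-tests, pause-activity correlation).
#'
#' @param study A `distraction_study` from [load_study()].
#' @param params A [trigger_params()].
#' @param epochs Epoch definitions (default [epoch_defs()]).
#' @param target_fs Snip decimation rate in Hz (default 10).
#' @param alpha Significance level (default 0.05).
#' @param roc_method Per-bin test for [binwise_roc()] (default "wilcox").
#' @param day_levels Names identifying the training, first distraction and
#'   habituation sessions (in that order).
#' @return A list of class `analysis_report`; see the package vignette for a
#'   tour of its components.
#' @export
run_full_analysis <- function(study, params = trigger_params(),
                              epochs = epoch_defs(), target_fs = 10,
                              alpha = 0.05, roc_method = "wilcox",
                              day_levels = c("lick", "distraction",
                                             "habituation")) {
  stopifnot(inherits(study, "distraction_study"))
  rep_out <- list()

  ## ---- behaviour -----------------------------------------------------
  trials_by_ses <- lapply(study, session_trials, params = params)
  trials <- do.call(rbind, trials_by_ses)
  trials$day <- factor(trials$day, levels = day_levels)
  rep_out$trials <- trials

  prob <- stats::aggregate(distracted ~ rat_id + day, data = trials,
                           FUN = mean)
  names(prob)[3] <- "p_distraction"
  rep_out$probability_by_day <- prob
  prob_wide <- stats::reshape(prob, idvar = "rat_id", timevar = "day",
                              direction = "wide")
  pm <- as.matrix(prob_wide[, -1, drop = FALSE])
  colnames(pm) <- sub("^p_distraction\\.", "", colnames(pm))
  pm <- pm[, day_levels, drop = FALSE]
  rep_out$probability_anova <- one_way_rm_anova(pm)

  rep_out$log_pause_anova <- log_pause_contrast(
    trials$post_pause, trials$rat_id, as.character(trials$day),
    censored = trials$censored_post)

  ok <- !trials$censored_post
  rep_out$pause_ecdf_by_day <- lapply(split(trials$post_pause, trials$day),
                                      pause_ecdf)

  ## pooled lick-rate ROC on the first distraction day
  d1 <- day_levels[2]
  lick_mats <- list()
  for (i in seq_along(study)) {
    ses <- study[[i]]
    if (ses$day != d1) next
    tr <- trials_by_ses[[i]]
    m <- suppressWarnings(peri_event_lick_rate(ses$licks, tr$time))
    keep <- tr$time - 5 >= 0 & tr$time + 15 <= ses$licks$session_end
    lick_mats[[length(lick_mats) + 1L]] <-
      list(rates = m, meta = tr[keep, , drop = FALSE])
  }
  rates <- do.call(rbind, lapply(lick_mats, `[[`, "rates"))
  lmeta <- do.call(rbind, lapply(lick_mats, `[[`, "meta"))
  bin_start <- seq(-5, 14)
  if (sum(lmeta$distracted) >= 2 && sum(!lmeta$distracted) >= 2) {
    rep_out$lickrate_roc <- binwise_roc(
      rates[!lmeta$distracted, , drop = FALSE],
      rates[lmeta$distracted, , drop = FALSE],
      alpha = alpha, method = roc_method, bin_start = bin_start)
  }

  ## per-rat pre/post mean lick rate, distracted vs not
  pre_cols <- which(bin_start >= -5 & bin_start < 0)
  post_cols <- which(bin_start >= 1 & bin_start < 15)
  rate_tab <- data.frame(
    rat_id = lmeta$rat_id, distracted = lmeta$distracted,
    pre = rowMeans(rates[, pre_cols, drop = FALSE]),
    post = rowMeans(rates[, post_cols, drop = FALSE]))
  agg <- stats::aggregate(cbind(pre, post) ~ rat_id + distracted,
                          data = rate_tab, FUN = mean)
  both <- intersect(agg$rat_id[agg$distracted], agg$rat_id[!agg$distracted])
  ad <- agg[agg$distracted & agg$rat_id %in% both, ]
  an <- agg[!agg$distracted & agg$rat_id %in% both, ]
  ad <- ad[order(ad$rat_id), ]; an <- an[order(an$rat_id), ]
  if (nrow(ad) >= 2) {
    rep_out$lickrate_pre_t <- paired_t(an$pre, ad$pre)
    rep_out$lickrate_post_t <- paired_t(an$post, ad$post)
  }

  ## pre-distractor pause, distracted vs not (pooled, day 1)
  t1 <- trials[trials$day == d1 & !trials$censored_pre &
                 !is.na(trials$pre_pause) & trials$pre_pause > 0, ]
  if (nrow(t1) > 3 && length(unique(t1$distracted)) == 2) {
    tt <- stats::t.test(log(t1$pre_pause[!t1$distracted]),
                        log(t1$pre_pause[t1$distracted]))
    rep_out$pre_pause_contrast <- list(
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
      median_not_distracted = stats::median(t1$pre_pause[!t1$distracted]),
      median_distracted = stats::median(t1$pre_pause[t1$distracted]))
    rep_out$baseline_event_fraction <- c(
      not_distracted = mean(t1$prior_event_in_baseline[!t1$distracted]),
      distracted = mean(t1$prior_event_in_baseline[t1$distracted]))
  }

  ## terciles of the first distraction day (behavioural habituation)
  ter <- lapply(split(trials[trials$day == d1, ], trials$rat_id[trials$day == d1]),
                function(tr) {
                  if (nrow(tr) < 3) return(NULL)
                  vapply(tercile_groups(tr), distraction_probability,
                         numeric(1))
                })
  ter <- do.call(rbind, ter[!vapply(ter, is.null, logical(1))])
  if (!is.null(ter) && nrow(ter) >= 3) {
    colnames(ter) <- c("t1", "t2", "t3")
    rep_out$tercile_behaviour_anova <- one_way_rm_anova(ter)
  }

  ## stimulus-type effectiveness (behaviour)
  st <- trials[trials$day == d1 & !is.na(trials$stimulus_label), ]
  if (nrow(st) > 0) {
    rep_out$stimulus_type_behaviour <- tryCatch(
      stimulus_type_contrast(st, st$rat_id), error = function(e) NULL)
  }

  ## ---- photometry ----------------------------------------------------
  has_pho <- all(vapply(study, function(s) !is.null(s$photometry),
                        logical(1)))
  if (!has_pho) {
    warning("photometry missing for some sessions; behavioural-only report",
            call. = FALSE)
    class(rep_out) <- "analysis_report"
    return(rep_out)
  }
  snp <- vector("list", length(study))
  for (i in seq_along(study)) {
    snp[[i]] <- session_snips(study[[i]], trials_by_ses[[i]],
                              target_fs = target_fs)
  }
  day_of <- vapply(study, `[[`, "", "day")
  rat_of <- vapply(study, `[[`, "", "rat_id")
  pool <- function(days, pred = NULL, what = "z_binned",
                   meta = "z_meta") {
    keep <- which(day_of %in% days)
    mats <- list(); metas <- list()
    for (i in keep) {
      m <- snp[[i]][[what]]; md <- snp[[i]][[meta]]
      if (!is.null(pred)) {
        sel <- pred(md)
        m <- m[sel, , drop = FALSE]; md <- md[sel, , drop = FALSE]
      }
      mats[[length(mats) + 1L]] <- m
      metas[[length(metas) + 1L]] <- md
    }
    list(mat = do.call(rbind, mats), meta = do.call(rbind, metas))
  }
  d0 <- day_levels[1]; d2 <- day_levels[3]
  bs <- seq(-5, 14)

  p_mod <- pool(d0); p_d1 <- pool(d1); p_d2 <- pool(d2)
  rep_out$roc_modelled_vs_day1 <- binwise_roc(
    p_mod$mat, p_d1$mat, alpha = alpha, method = roc_method, bin_start = bs)
  p_nd <- pool(d1, function(md) !md$distracted)
  p_dd <- pool(d1, function(md) md$distracted)
  rep_out$roc_distracted_vs_not <- binwise_roc(
    p_nd$mat, p_dd$mat, alpha = alpha, method = roc_method, bin_start = bs)
  rep_out$roc_day1_vs_day2 <- binwise_roc(
    p_d1$mat, p_d2$mat, alpha = alpha, method = roc_method, bin_start = bs)
  p_dd2 <- pool(d2, function(md) md$distracted)
  p_nd2 <- pool(d2, function(md) !md$distracted)
  if (nrow(p_dd2$mat) >= 2 && nrow(p_dd$mat) >= 2) {
    rep_out$roc_day1_vs_day2_distracted <- binwise_roc(
      p_dd$mat, p_dd2$mat, alpha = alpha, method = roc_method,
      bin_start = bs)
  }
  if (nrow(p_nd2$mat) >= 2 && nrow(p_nd$mat) >= 2) {
    rep_out$roc_day1_vs_day2_not_distracted <- binwise_roc(
      p_nd$mat, p_nd2$mat, alpha = alpha, method = roc_method,
      bin_start = bs)
  }

  ## epoch summaries and RM-ANOVAs
  ep_rows <- list()
  for (i in seq_along(study)) {
    s <- snp[[i]]
    for (norm in c("z", "raw")) {
      obj <- s[[norm]]
      md <- s[[paste0(norm, "_meta")]]
      em <- epoch_means(obj, epochs,
                        rat_id = rep(rat_of[i], nrow(obj$data)),
                        condition = rep(day_of[i], nrow(obj$data)))
      em$normalized <- norm == "z"
      ep_rows[[length(ep_rows) + 1L]] <- em
      if (day_of[i] %in% c(d1, d2) && length(unique(md$distracted)) == 2) {
        em2 <- epoch_means(obj, epochs,
                           rat_id = rep(rat_of[i], nrow(obj$data)),
                           condition = ifelse(md$distracted, "distracted",
                                              "not_distracted"))
        em2$condition <- paste0(day_of[i], ":", em2$condition)
        em2$normalized <- norm == "z"
        ep_rows[[length(ep_rows) + 1L]] <- em2
      }
    }
  }
  ep_tab <- do.call(rbind, ep_rows)
  rep_out$epoch_summaries <- ep_tab
  rats <- sort(unique(rat_of))
  epn <- names(epochs)

  z_tab <- ep_tab[ep_tab$normalized, ]
  arr <- epoch_array(z_tab[z_tab$condition %in% c(d0, d1), ], rats, epn,
                     c(d0, d1))
  if (!anyNA(arr)) rep_out$epoch_day_anova <- two_way_rm_anova(arr)
  arr2 <- epoch_array(z_tab[z_tab$condition %in%
                              paste0(d1, ":", c("not_distracted",
                                                "distracted")), ],
                      rats, epn,
                      paste0(d1, ":", c("not_distracted", "distracted")))
  if (!anyNA(arr2)) rep_out$epoch_trialtype_anova <- two_way_rm_anova(arr2)
  raw_tab <- ep_tab[!ep_tab$normalized, ]
  arr3 <- epoch_array(raw_tab[raw_tab$condition %in%
                                paste0(d1, ":", c("not_distracted",
                                                  "distracted")), ],
                      rats, epn,
                      paste0(d1, ":", c("not_distracted", "distracted")))
  if (!anyNA(arr3)) {
    rep_out$epoch_trialtype_anova_nonz <- two_way_rm_anova(arr3)
  }

  ## session RMS and non-z baseline/post comparisons across distraction days
  rms1 <- vapply(which(day_of == d1), function(i) session_rms(snp[[i]]$trace),
                 numeric(1))[order(rat_of[day_of == d1])]
  rms2 <- vapply(which(day_of == d2), function(i) session_rms(snp[[i]]$trace),
                 numeric(1))[order(rat_of[day_of == d2])]
  rep_out$rms_t <- paired_t(rms1, rms2)
  for (ep in c("pre", "early_post")) {
    a <- raw_tab[raw_tab$condition == d1 & raw_tab$epoch == ep, ]
    b <- raw_tab[raw_tab$condition == d2 & raw_tab$epoch == ep, ]
    a <- a[order(a$rat_id), ]; b <- b[order(b$rat_id), ]
    if (nrow(a) == nrow(b) && nrow(a) >= 2) {
      rep_out[[paste0("nonz_", ep, "_t")]] <- paired_t(a$value, b$value)
    }
  }

  ## neural terciles (early post-event z by tercile, first distraction day)
  tern <- list()
  for (i in which(day_of == d1)) {
    md <- snp[[i]]$z_meta
    if (nrow(md) < 3) next
    em <- epoch_means(snp[[i]]$z, epochs)
    ev <- em$value[em$epoch == "early_post"]
    g <- tercile_groups(data.frame(idx = seq_along(ev)))
    tern[[rat_of[i]]] <- vapply(g, function(gg) mean(ev[gg$idx]), numeric(1))
  }
  if (length(tern) >= 3) {
    tm <- do.call(rbind, tern)
    colnames(tm) <- c("t1", "t2", "t3")
    rep_out$tercile_neural_anova <- one_way_rm_anova(tm)
  }

  ## stimulus-type effect on evoked activity
  st_rows <- list()
  for (i in which(day_of == d1)) {
    md <- snp[[i]]$z_meta
    em <- epoch_means(snp[[i]]$z, epochs)
    ev <- em$value[em$epoch == "early_post"]
    st_rows[[length(st_rows) + 1L]] <- data.frame(
      rat = rat_of[i], cls = stimulus_class(md$stimulus_label), v = ev)
  }
  st_tab <- do.call(rbind, st_rows)
  if (!is.null(st_tab) && nrow(st_tab) > 0) {
    agg <- stats::aggregate(v ~ rat + cls, data = st_tab, FUN = mean,
                            drop = FALSE)
    wide <- stats::reshape(agg, idvar = "rat", timevar = "cls",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    colnames(m) <- sub("^v\\.", "", colnames(m))
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) >= 3) {
      rep_out$stimulus_type_neural <- one_way_rm_anova(m)
    }
  }

  ## pause-activity correlation on distracted day-1 trials
  cor_rows <- list()
  for (i in which(day_of == d1)) {
    md <- snp[[i]]$z_meta
    zz <- snp[[i]]$z
    cols <- snip_cols(zz, 0, 3)
    ev <- rowMeans(zz$data[, cols, drop = FALSE])
    sel <- md$distracted & !md$censored_post
    cor_rows[[length(cor_rows) + 1L]] <- data.frame(
      pause = md$post_pause[sel], evoked = ev[sel])
  }
  ct <- do.call(rbind, cor_rows)
  if (!is.null(ct) && nrow(ct) >= 3) {
    rep_out$pause_activity_cor <- pause_activity_correlation(ct$pause,
                                                             ct$evoked)
  }

  class(rep_out) <- "analysis_report"
  rep_out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> components:\n")
  cat(paste(" -", names(x)), sep = "\n")
  invisible(x)
}

#' Flatten a report into tidy CSV tables
#'
#' Writes the report's main tables (trials, probabilities, ROC panels, epoch
#' summaries) as tidy CSV files into `out_dir`.
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the vector of written file paths.
#' @export
write_report_tables <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    data.table::fwrite(as.data.frame(df), p)
    paths <<- c(paths, p)
  }
  for (nm in names(report)) {
    obj <- report[[nm]]
    if (is.data.frame(obj)) emit(obj, nm)
  }
  invisible(paths)
}
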