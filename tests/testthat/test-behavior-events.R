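test_that("lick_train validates and cleans its input", {
  expect_error(lick_train(c(2, 1)), "sorted")
  expect_error(lick_train(c(-1, 2)), "within")
  expect_error(lick_train(c(1, 2), session_end = 1.5), "within")
  expect_warning(lt <- lick_train(c(1, 1, 2)), "duplicate")
  expect_equal(lt$onsets, c(1, 2))
  expect_error(lick_train(c(1, 2), offsets = c(1.1, 1.9)), "offset")
  lt2 <- lick_train(c(1, 2), offsets = c(1.05, 2.05))
  expect_equal(lt2$offsets, c(1.05, 2.05))
})

test_that("trigger detection reproduces worked examples", {
  p <- trigger_params()
  tr <- detect_trigger_events(lick_train(c(0, 0.2, 0.4, 0.6, 3)), p)
  expect_equal(tr$time, 0.4)
  expect_equal(tr$burst_position, 3L)
  expect_equal(nrow(detect_trigger_events(lick_train(numeric(0)), p)), 0)
  # third lick 1.2 s after the first: the triple spans more than the window
  expect_equal(nrow(detect_trigger_events(lick_train(c(0, 0.5, 1.2)), p)), 0)
  # slow early triple, trigger lands later in the burst (position 4)
  tr4 <- detect_trigger_events(lick_train(c(0, 0.6, 1.2, 1.5, 5)), p)
  expect_equal(tr4$burst_position, 4L)
  expect_equal(tr4$time, 1.5)
})

test_that("trigger detection matches the brute-force scan on random trains", {
  set.seed(101)
  p <- trigger_params()
  for (rep in 1:300) {
    t <- random_lick_train(120)
    got <- detect_trigger_events(lick_train(t, session_end = max(t) + 1), p)
    want <- oracle_triggers(t)
    expect_identical(got$lick_index, want$lick_index)
    expect_equal(got$time, want$time)
    expect_identical(got$burst_position, want$burst_position)
  }
})

test_that("consecutive triggers are separated by a long inter-lick interval", {
  set.seed(77)
  p <- trigger_params()
  for (rep in 1:50) {
    t <- random_lick_train(200)
    tr <- detect_trigger_events(lick_train(t, session_end = max(t) + 1), p)
    if (nrow(tr) < 2) next
    for (i in 2:nrow(tr)) {
      gaps <- diff(t[tr$lick_index[i - 1]:tr$lick_index[i]])
      expect_true(any(gaps > p$eligibility_pause))
    }
  }
})

test_that("distraction classification follows the pause rule and censors", {
  lt <- lick_train(c(1, 1.1, 1.2, 10), session_end = 50)
  r <- classify_distraction(lt, 1.2)
  expect_equal(r$post_pause, 8.8)
  expect_true(r$distracted)
  expect_false(r$censored)
  r2 <- classify_distraction(lt, 9.7)
  expect_equal(r2$post_pause, 0.3, tolerance = 1e-12)
  expect_false(r2$distracted)
  # no lick after the event: censored at session end, distracted
  r3 <- classify_distraction(lt, 10)
  expect_equal(r3$post_pause, 40)
  expect_true(r3$distracted)
  expect_true(r3$censored)
  expect_error(classify_distraction(lt, 60), "outside")
})

test_that("raising the threshold never creates new distracted trials", {
  set.seed(5)
  for (rep in 1:50) {
    t <- random_lick_train(80)
    lt <- lick_train(t, session_end = max(t) + 5)
    ev <- stats::runif(1, 0, max(t))
    d <- vapply(c(0.5, 1, 2, 4), function(th) {
      classify_distraction(lt, ev, th)$distracted
    }, logical(1))
    expect_true(all(diff(as.integer(d)) <= 0))
  }
})

test_that("pre-distractor pause measures the gap before the burst", {
  p <- trigger_params()
  lt <- lick_train(c(5, 8, 8.2, 8.4), session_end = 60)
  tr <- detect_trigger_events(lt, p)
  expect_equal(tr$time, 8.4)
  pp <- pre_distractor_pause(lt, tr$lick_index, p)
  expect_equal(pp$pre_pause, 3)
  expect_false(pp$censored)
  # session's first burst: left-censored at the burst start
  lt2 <- lick_train(c(12, 12.1, 12.2), session_end = 60)
  tr2 <- detect_trigger_events(lt2, p)
  pp2 <- pre_distractor_pause(lt2, tr2$lick_index, p)
  expect_equal(pp2$pre_pause, 12)
  expect_true(pp2$censored)
  # gap just above the eligibility pause is measured as-is
  lt3 <- lick_train(c(2, 3.001, 3.1, 3.2), session_end = 60)
  tr3 <- detect_trigger_events(lt3, p)
  pp3 <- pre_distractor_pause(lt3, tr3$lick_index, p)
  expect_equal(pp3$pre_pause, 1.001, tolerance = 1e-9)
})

test_that("build_trials assembles pauses, flags and burst positions", {
  p <- trigger_params()
  expect_equal(nrow(build_trials(lick_train(c(1, 2)), data.frame(time = numeric(0)), p)), 0)
  set.seed(31)
  t <- random_lick_train(150)
  lt <- lick_train(t, session_end = max(t) + 10)
  trig <- detect_trigger_events(lt, p)
  expect_gt(nrow(trig), 0)
  trials <- build_trials(lt, data.frame(time = trig$time), p)
  expect_true(all(trials$burst_position >= 3))
  expect_equal(trials$time, trig$time)
  # distracted flag consistent with the classification rule
  for (i in seq_len(nrow(trials))) {
    cl <- classify_distraction(lt, trials$time[i], p$distraction_threshold)
    expect_equal(trials$post_pause[i], cl$post_pause)
    expect_equal(trials$distracted[i], cl$distracted)
  }
  # an external event off any trigger lick is flagged
  expect_warning(
    tr2 <- build_trials(lt, data.frame(time = trig$time[1] + 1e-4), p),
    "no identifiable")
  expect_true(is.na(tr2$burst_position[1]))
})

test_that("distraction probability is the distracted fraction", {
  tr <- data.frame(distracted = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(distraction_probability(tr), 0.4)
  expect_equal(distraction_probability(data.frame(distracted = rep(TRUE, 4))), 1)
  expect_error(distraction_probability(data.frame(distracted = logical(0))),
               "empty")
})

test_that("peri-event lick rates count licks in half-open 1-s bins", {
  lt <- lick_train(c(10.1, 10.2, 10.9, 11.0), session_end = 100)
  m <- peri_event_lick_rate(lt, 10)
  expect_equal(dim(m), c(1, 20))
  expect_equal(attr(m, "bin_start"), seq(-5, 14))
  expect_equal(m[1, 6], 3)  # [0, 1): licks at +0.1, +0.2, +0.9
  expect_equal(m[1, 7], 1)  # [1, 2): lick at exactly +1.0
  expect_equal(unname(m[1, 1:5]), rep(0, 5))
  # translation equivariance: shifting licks by +1 s shifts the histogram
  lt2 <- lick_train(lt$onsets + 1, session_end = 100)
  m2 <- peri_event_lick_rate(lt2, 10)
  expect_equal(m2[1, 7], 3)
  # events too close to the session edge are dropped with a warning
  expect_warning(m3 <- peri_event_lick_rate(lt, c(2, 10)), "dropped")
  expect_equal(nrow(m3), 1)
})

test_that("terciles split chronologically with the remainder rule", {
  tr <- data.frame(time = 1:11, distracted = rep(TRUE, 11))
  g <- tercile_groups(tr[1:9, ])
  expect_equal(vapply(g, nrow, integer(1)), c(`1` = 3L, `2` = 3L, `3` = 3L))
  g10 <- tercile_groups(tr[1:10, ])
  expect_equal(unname(vapply(g10, nrow, integer(1))), c(4L, 3L, 3L))
  g11 <- tercile_groups(tr)
  expect_equal(unname(vapply(g11, nrow, integer(1))), c(4L, 4L, 3L))
  expect_equal(g11[[1]]$time, 1:4)  # contiguous and in order
  expect_error(tercile_groups(tr[1:2, ]), "at least 3")
})

test_that("pause ECDF matches rank computation and is a proper CDF", {
  f <- pause_ecdf(c(1, 2, 3))
  expect_equal(f(2), 2 / 3)
  expect_equal(f(3), 1)
  set.seed(8)
  x <- stats::rlnorm(200)
  f2 <- pause_ecdf(x)
  q <- stats::runif(20, 0, max(x))
  for (v in q) expect_equal(f2(v), mean(x <= v))
  expect_true(all(diff(f2(sort(q))) >= 0))
  expect_error(pause_ecdf(numeric(0)), "no pauses")
})
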