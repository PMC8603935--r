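test_that("pairwise AUC reproduces worked examples and identities", {
  expect_equal(pairwise_auc(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(pairwise_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(pairwise_auc(c(1, 3), c(2, 4)), 0.75)
  expect_error(pairwise_auc(numeric(0), 1), "non-empty")
})

test_that("pairwise AUC equals brute-force pair counting with ties", {
  set.seed(11)
  for (rep in 1:400) {
    a <- sample(0:6, sample(2:10, 1), replace = TRUE) +
      sample(c(0, 0.5), 1)  # mix of tied and untied configurations
    b <- sample(0:6, sample(2:10, 1), replace = TRUE)
    expect_equal(pairwise_auc(a, b), oracle_auc(a, b), tolerance = 1e-12)
    # orientation identity
    expect_equal(pairwise_auc(a, b) + pairwise_auc(b, a), 1,
                 tolerance = 1e-12)
  }
})

test_that("binwise ROC flags exactly the separated bins", {
  set.seed(12)
  A <- matrix(stats::rnorm(30 * 20), 30, 20)
  # duplicated group: AUC 0.5 everywhere, nothing significant
  r0 <- binwise_roc(A, A)
  expect_true(all(r0$auc == 0.5))
  expect_false(any(r0$significant))
  # large shift confined to bins 6-9
  B <- matrix(stats::rnorm(30 * 20), 30, 20)
  B[, 6:9] <- B[, 6:9] + 10
  r <- binwise_roc(A, B)
  expect_identical(which(r$significant), 6:9)
  expect_true(all(r$auc[6:9] > 0.99))
  expect_true(all(r$p_adj >= r$p_raw))
  expect_true(all(r$p_adj <= 1 & r$p_raw >= 0))
  expect_equal(r$p_adj, pmin(1, 20 * r$p_raw))
  expect_error(binwise_roc(A, B[, 1:10]), "same number of bins")
})

test_that("permutation and t-test alternatives agree on strong effects", {
  set.seed(13)
  A <- matrix(stats::rnorm(20 * 4), 20, 4)
  B <- matrix(stats::rnorm(20 * 4), 20, 4)
  B[, 2] <- B[, 2] + 8
  rp <- binwise_roc(A, B, method = "permutation", n_perm = 400)
  rt <- binwise_roc(A, B, method = "ttest")
  expect_true(rp$significant[2] && rt$significant[2])
  expect_false(any(rp$significant[-2]) || any(rt$significant[-2]))
})

test_that("one-way RM-ANOVA matches the sums-of-squares oracle", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(3:8, 1); k <- sample(3:5, 1)
    m <- matrix(stats::rnorm(n * k, sd = sample(1:3, 1)), n, k)
    r <- one_way_rm_anova(m)
    expect_equal(r$statistic, oracle_rm1_F(m), tolerance = 1e-8)
    expect_equal(r$df, c(k - 1, (k - 1) * (n - 1)))
    # adding per-subject offsets is absorbed by the subject stratum
    m2 <- m + stats::rnorm(n, sd = 5)
    expect_equal(one_way_rm_anova(m2)$statistic, r$statistic,
                 tolerance = 1e-8)
  }
  # hand-computable table
  m <- rbind(c(1, 2, 3), c(2, 3, 5), c(0, 1, 2), c(1, 1, 4))
  expect_equal(one_way_rm_anova(m)$statistic, oracle_rm1_F(m),
               tolerance = 1e-10)
  # identical columns: no condition effect at all
  mi <- matrix(rep(stats::rnorm(4), 3), 4, 3)
  ri <- one_way_rm_anova(mi)
  expect_equal(ri$statistic, 0)
  expect_equal(ri$p, 1)
  expect_true(all(ri$posthoc$p_adj == 1))
  expect_error(one_way_rm_anova(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)),
               "complete")
})

test_that("two-way RM-ANOVA interaction matches the oracle decomposition", {
  set.seed(15)
  for (rep in 1:15) {
    n <- sample(3:6, 1); a <- sample(2:4, 1); b <- sample(2:3, 1)
    arr <- array(stats::rnorm(n * a * b), dim = c(n, a, b))
    r <- two_way_rm_anova(arr)
    expect_equal(r$statistic, oracle_rm2_interaction_F(arr),
                 tolerance = 1e-8)
    expect_equal(r$df, c((a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1)))
  }
  # additive data: no interaction beyond noise-free zero
  n <- 5
  subj <- stats::rnorm(n)
  arr_add <- array(0, dim = c(n, 3, 2))
  for (j in 1:3) for (k in 1:2) arr_add[, j, k] <- subj + j * 0.5 + k * 2
  expect_equal(two_way_rm_anova(arr_add)$statistic, 0)
  # crossover: condition effect in one epoch only gives a large interaction
  arr_x <- array(stats::rnorm(5 * 3 * 2, sd = 0.1), dim = c(5, 3, 2),
                 dimnames = list(NULL, c("pre", "early", "late"),
                                 c("c1", "c2")))
  arr_x[, "early", "c2"] <- arr_x[, "early", "c2"] + 5
  rx <- two_way_rm_anova(arr_x)
  expect_gt(rx$statistic, 50)
  expect_lt(rx$p, 0.001)
  # Sidak adjustment follows its closed form
  expect_equal(rx$posthoc$p_adj,
               1 - (1 - rx$posthoc$p_raw)^nrow(rx$posthoc))
  expect_true(all(rx$posthoc$p_adj >= rx$posthoc$p_raw))
})

test_that("paired t follows the textbook formula and its symmetries", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1.2, 1.9, 3.4, 4.4, 5.5)
  r <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (stats::sd(d) / sqrt(5))
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * stats::pt(-abs(t_hand), 4), tolerance = 1e-12)
  # sign flip of the differences negates t, preserves p
  r2 <- paired_t(y, x)
  expect_equal(r2$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(r2$p, r$p, tolerance = 1e-12)
  # identical vectors
  r3 <- paired_t(x, x)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p, 1)
  expect_error(paired_t(1:3, 1:4), "paired")
})

test_that("log-pause day contrast detects injected day effects", {
  set.seed(16)
  n_rat <- 12
  rats <- rep(sprintf("r%02d", 1:n_rat), each = 60)
  day <- rep(rep(c("d1", "d2", "d3"), each = 20), n_rat)
  base <- stats::rlnorm(length(rats), log(2), 0.5)
  # no day effect: F should be unremarkable under the null
  r0 <- log_pause_contrast(base, rats, day)
  expect_gt(r0$p, 0.001)
  # scale day 2 pauses up threefold: a large within-subject effect
  scaled <- base * ifelse(day == "d2", 3, 1)
  r1 <- log_pause_contrast(scaled, rats, day)
  expect_lt(r1$p, 0.05)
  # identical pauses across days: exactly zero F
  same <- rep(2, length(rats))
  r2 <- log_pause_contrast(same, rats, day)
  expect_equal(r2$statistic, 0)
  # non-positive pauses are excluded with a warning
  bad <- scaled; bad[1] <- 0
  expect_warning(log_pause_contrast(bad, rats, day), "non-positive")
})

test_that("pause-activity correlation behaves at its extremes", {
  p <- c(1.5, 2, 3, 5, 8)
  r <- pause_activity_correlation(p, log(p))
  expect_equal(r$statistic, 1, tolerance = 1e-12)
  set.seed(17)
  r0 <- pause_activity_correlation(stats::rlnorm(100, log(3), 0.5),
                                   stats::rnorm(100))
  expect_lt(abs(r0$statistic), 0.2)  # inside the null band for n = 100
  expect_error(pause_activity_correlation(p, rep(1, 5)), "constant")
  expect_error(pause_activity_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("stimulus classes partition trials and detect boosted classes", {
  labs <- distractor_labels()
  cls <- lickdistract:::stimulus_class(labs)
  expect_false(anyNA(cls))
  expect_equal(sort(unique(as.character(cls))),
               c("other", "tone", "white_noise"))
  # every label lands in exactly one class
  expect_equal(length(cls), length(labs))
  set.seed(18)
  n_rat <- 8
  trials <- do.call(rbind, lapply(1:n_rat, function(r) {
    lab <- sample(labs, 90, replace = TRUE)
    cl <- lickdistract:::stimulus_class(lab)
    p <- c(white_noise = 0.7, tone = 0.4, other = 0.4)[as.character(cl)]
    data.frame(rat = sprintf("r%d", r), stimulus_label = lab,
               distracted = stats::runif(90) < p)
  }))
  r <- stimulus_type_contrast(trials, trials$rat)
  expect_lt(r$p, 0.05)
  # flat probabilities: an unremarkable F
  trials$distracted <- stats::runif(nrow(trials)) < 0.5
  r0 <- stimulus_type_contrast(trials, trials$rat)
  expect_gt(r0$p, 0.001)
})
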