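# Independent reference implementations used to check the package's fast
# paths. These are deliberately literal and quadratic; they never share code
# with the implementation under test.

# Literal scan of the trigger rule: for every lick, find its maximal run by
# walking backwards, then apply the burst-position / window / re-arm
# conditions directly.
oracle_triggers <- function(t, k = 3, window = 1, elig = 1) {
  fired_at <- integer(0)
  out_time <- numeric(0); out_pos <- integer(0); out_idx <- integer(0)
  for (i in seq_along(t)) {
    s <- i
    while (s > 1 && t[s] - t[s - 1] <= elig) s <- s - 1L
    j <- i - s + 1L
    if (j < k) next
    if (t[i] - t[i - k + 1L] > window) next
    if (any(fired_at >= s)) next  # trigger already delivered in this run
    fired_at <- c(fired_at, i)
    out_time <- c(out_time, t[i])
    out_pos <- c(out_pos, j)
    out_idx <- c(out_idx, i)
  }
  data.frame(time = out_time, burst_position = out_pos, lick_index = out_idx)
}

# Random lick train with burst/pause structure plus occasional irregular
# gaps, so runs of every length and near-boundary intervals all occur.
random_lick_train <- function(max_licks = 200) {
  n <- sample.int(max_licks, 1)
  gaps <- sample(c(stats::runif(n, 0.05, 0.4),
                   stats::runif(n, 0.8, 1.3),
                   stats::rexp(n, 1 / 3)), n)
  cumsum(gaps)
}

# AUC by explicit double loop over all pairs, with ties counted half.
oracle_auc <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) {
    tot <- tot + (y > x) + 0.5 * (y == x)
  }
  tot / (length(a) * length(b))
}

# One-way within-subject F via the textbook sums-of-squares decomposition.
oracle_rm1_F <- function(m) {
  n <- nrow(m); k <- ncol(m); g <- mean(m)
  ss_cond <- n * sum((colMeans(m) - g)^2)
  ss_subj <- k * sum((rowMeans(m) - g)^2)
  ss_err <- sum((m - g)^2) - ss_cond - ss_subj
  (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

# Interaction F of a subjects x a x b within-subject design via the full
# decomposition of the three-way (subject x factor x factor) table.
oracle_rm2_interaction_F <- function(arr) {
  n <- dim(arr)[1]; a <- dim(arr)[2]; b <- dim(arr)[3]
  cell <- apply(arr, c(2, 3), mean)
  Aj <- rowMeans(cell); Bk <- colMeans(cell); G <- mean(arr)
  ss_int <- n * sum((cell - outer(Aj, rep(1, b)) -
                       outer(rep(1, a), Bk) + G)^2)
  x_ij <- apply(arr, c(1, 2), mean)
  x_ik <- apply(arr, c(1, 3), mean)
  x_i <- apply(arr, 1, mean)
  res <- arr
  for (i in seq_len(n)) for (j in seq_len(a)) for (kk in seq_len(b)) {
    res[i, j, kk] <- arr[i, j, kk] - cell[j, kk] - x_ij[i, j] - x_ik[i, kk] +
      Aj[j] + Bk[kk] + x_i[i] - G
  }
  ss_err <- sum(res^2)
  (ss_int / ((a - 1) * (b - 1))) / (ss_err / ((a - 1) * (b - 1) * (n - 1)))
}

# small desk-scale generator config shared across tests
test_config <- function(seed, session_length = 600, fs = 50, ...) {
  synth_config(seed = seed, session_length = session_length,
               photometry = photometry_defaults(fs = fs), ...)
}
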