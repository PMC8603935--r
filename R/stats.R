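#' Pairwise AUC of two groups
#'
#' The area under the ROC curve comparing group B against group A:
#' `P(b > a) + 0.5 P(b == a)` over all pairs, computed from the rank-sum
#' (Mann-Whitney U) statistic. Values above 0.5 mean B tends to exceed A.
#'
#' @param valsA Numeric vector, reference group.
#' @param valsB Numeric vector, comparison group.
#' @return AUC in \[0, 1\].
#' @examples
#' pairwise_auc(c(1, 2, 3), c(4, 5, 6))  # 1
#' pairwise_auc(c(1, 3), c(2, 4))        # 0.75
#' @export
pairwise_auc <- function(valsA, valsB) {
  nA <- length(valsA); nB <- length(valsB)
  if (nA == 0 || nB == 0) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(valsA, valsB))
  (sum(r[(nA + 1):(nA + nB)]) - nB * (nB + 1) / 2) / (nA * nB)
}

# paired t that tolerates zero-variance differences (t.test refuses them)
paired_t_stat <- function(x, y) {
  d <- x - y
  n <- length(d)
  constant <- function() {
    if (abs(mean(d)) < 1e-12 * max(abs(x), 1)) {
      c(t = 0, df = n - 1, p_raw = 1)
    } else {
      c(t = sign(mean(d)) * Inf, df = n - 1, p_raw = 0)
    }
  }
  if (stats::sd(d) == 0) return(constant())
  tryCatch({
    tt <- stats::t.test(x, y, paired = TRUE)
    c(t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value)
  }, error = function(e) constant())  # differences constant up to rounding
}

# two-sided p for group difference in one bin; a bin where every trial in
# both groups has the same value carries no evidence (p = 1)
bin_p <- function(a, b, method, n_perm) {
  if (length(unique(c(a, b))) == 1) return(1)
  if (method == "wilcox") {
    p <- suppressWarnings(stats::wilcox.test(b, a)$p.value)
    if (is.na(p)) p <- 1
    p
  } else if (method == "ttest") {
    p <- tryCatch(stats::t.test(b, a)$p.value, error = function(e) NA_real_)
    if (is.na(p)) p <- 1
    p
  } else {
    obs <- abs(pairwise_auc(a, b) - 0.5)
    pool <- c(a, b)
    nA <- length(a)
    hits <- 0L
    for (k in seq_len(n_perm)) {
      idx <- sample.int(length(pool), nA)
      if (abs(pairwise_auc(pool[idx], pool[-idx]) - 0.5) >= obs - 1e-12) {
        hits <- hits + 1L
      }
    }
    (1 + hits) / (n_perm + 1)
  }
}

#' Bin-wise ROC comparison of two trial groups
#'
#' For every time bin, computes the AUC between the two groups' per-trial
#' values and a two-sided p-value, then applies Bonferroni correction across
#' the bins (one analysis panel = one comparison family). Default p-values
#' come from the Mann-Whitney U test, the test whose statistic the AUC
#' normalises (exact for small samples without ties, tie-corrected normal
#' approximation otherwise); Welch t and label-permutation p-values are
#' available as alternatives.
#'
#' @param matA Matrix `trials x bins`, group A (reference).
#' @param matB Matrix `trials x bins`, group B.
#' @param alpha Family-wise significance level (default 0.05).
#' @param method `"wilcox"` (default), `"ttest"` or `"permutation"`.
#' @param n_perm Permutations when `method = "permutation"` (default 10000).
#' @param bin_start Optional bin left edges; taken from the `bin_start`
#'   attribute of `matA` when present.
#' @return A data.frame of class `roc_bin_result`: `bin_start`, `auc`,
#'   `p_raw`, `p_adj`, `significant`; attributes `n_A`, `n_B`, `alpha`,
#'   `method`.
#' @export
binwise_roc <- function(matA, matB, alpha = 0.05,
                        method = c("wilcox", "ttest", "permutation"),
                        n_perm = 10000, bin_start = NULL) {
  method <- match.arg(method)
  if (ncol(matA) != ncol(matB)) {
    stop("groups must have the same number of bins", call. = FALSE)
  }
  if (nrow(matA) < 2 || nrow(matB) < 2) {
    stop("each group needs at least 2 trials", call. = FALSE)
  }
  m <- ncol(matA)
  if (is.null(bin_start)) bin_start <- attr(matA, "bin_start")
  if (is.null(bin_start)) bin_start <- seq_len(m) - 1
  auc <- p_raw <- numeric(m)
  for (b in seq_len(m)) {
    a <- matA[, b]; bb <- matB[, b]
    auc[b] <- pairwise_auc(a, bb)
    p_raw[b] <- bin_p(a, bb, method, n_perm)
  }
  p_adj <- pmin(1, m * p_raw)
  out <- data.frame(bin_start = bin_start, auc = auc, p_raw = p_raw,
                    p_adj = p_adj, significant = p_adj < alpha)
  attr(out, "n_A") <- nrow(matA)
  attr(out, "n_B") <- nrow(matB)
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  class(out) <- c("roc_bin_result", "data.frame")
  out
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA on a complete `subjects x conditions` table,
#' with F on `(k - 1, (k - 1)(n - 1))` degrees of freedom, plus
#' Bonferroni-corrected paired-t post-hoc contrasts for every condition pair.
#'
#' @param values Numeric matrix or data.frame, `subjects x conditions`
#'   (column names are the condition labels).
#' @return A list of class `stat_result`: `test`, `statistic` (F), `df`
#'   (numerator, denominator), `p`, `correction`, and `posthoc`, a data.frame
#'   with `contrast`, `t`, `df`, `p_raw`, `p_adj`.
#' @export
one_way_rm_anova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("complete cases required", call. = FALSE)
  n <- nrow(values); k <- ncol(values)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (is.null(colnames(values))) colnames(values) <- paste0("c", seq_len(k))
  d <- data.frame(
    y = as.vector(values),
    subj = factor(rep(seq_len(n), times = k)),
    cond = factor(rep(colnames(values), each = n), levels = colnames(values))
  )
  fit <- stats::aov(y ~ cond + Error(subj / cond), data = d)
  tab <- summary(fit)[["Error: subj:cond"]][[1]]
  Fv <- tab["cond", "F value"]
  df1 <- tab["cond", "Df"]
  df2 <- tab["Residuals", "Df"]
  p <- tab["cond", "Pr(>F)"]
  ss_tot <- sum((values - mean(values))^2)
  if (is.na(Fv) || ss_tot == 0 ||
      tab["cond", "Sum Sq"] < 1e-12 * ss_tot) {
    Fv <- 0; p <- 1  # no between-condition variance beyond rounding
  }
  pairs <- utils::combn(colnames(values), 2)
  ph <- apply(pairs, 2, function(pr) {
    paired_t_stat(values[, pr[1]], values[, pr[2]])
  })
  posthoc <- data.frame(
    contrast = paste(pairs[1, ], pairs[2, ], sep = " vs "),
    t = ph["t", ], df = ph["df", ], p_raw = ph["p_raw", ],
    p_adj = pmin(1, ncol(pairs) * ph["p_raw", ])
  )
  structure(
    list(test = "one-way RM-ANOVA", statistic = unname(Fv),
         df = c(df1, df2), p = unname(p), correction = "bonferroni",
         posthoc = posthoc, n = n),
    class = "stat_result"
  )
}

#' Two-way repeated-measures ANOVA (interaction)
#'
#' Fully-crossed within-subject two-way ANOVA, reporting the
#' epoch-by-condition interaction F on
#' `((a - 1)(b - 1), (a - 1)(b - 1)(n - 1))` degrees of freedom, with
#' Sidak-adjusted paired condition contrasts within each epoch.
#'
#' @param values 3-d array `subjects x epochs x conditions`, with dimnames on
#'   the epoch and condition margins.
#' @return A `stat_result` list; `posthoc` has one row per epoch and
#'   condition pair with Sidak-adjusted p (`p_adj = 1 - (1 - p)^m`, `m` =
#'   total number of contrasts).
#' @export
two_way_rm_anova <- function(values) {
  stopifnot(length(dim(values)) == 3)
  if (anyNA(values)) stop("design must be complete and balanced", call. = FALSE)
  n <- dim(values)[1]; a <- dim(values)[2]; b <- dim(values)[3]
  ep <- dimnames(values)[[2]]; if (is.null(ep)) ep <- paste0("e", seq_len(a))
  co <- dimnames(values)[[3]]; if (is.null(co)) co <- paste0("c", seq_len(b))
  dimnames(values) <- list(dimnames(values)[[1]], ep, co)
  d <- data.frame(
    y = as.vector(values),
    subj = factor(rep(seq_len(n), times = a * b)),
    epoch = factor(rep(rep(ep, each = n), times = b), levels = ep),
    cond = factor(rep(co, each = n * a), levels = co)
  )
  fit <- stats::aov(
    y ~ epoch * cond + Error(subj / (epoch * cond)), data = d)
  tab <- summary(fit)[["Error: subj:epoch:cond"]][[1]]
  Fv <- tab["epoch:cond", "F value"]
  p <- tab["epoch:cond", "Pr(>F)"]
  ss_tot <- sum((values - mean(values))^2)
  if (is.na(Fv) || ss_tot == 0 ||
      tab["epoch:cond", "Sum Sq"] < 1e-12 * ss_tot) {
    Fv <- 0; p <- 1
  }
  pairs <- utils::combn(co, 2, simplify = FALSE)
  rows <- list()
  for (e in ep) {
    for (pr in pairs) {
      st <- paired_t_stat(values[, e, pr[1]], values[, e, pr[2]])
      rows[[length(rows) + 1L]] <- data.frame(
        epoch = e, contrast = paste(pr[1], "vs", pr[2]),
        t = st[["t"]], df = st[["df"]], p_raw = st[["p_raw"]])
    }
  }
  posthoc <- do.call(rbind, rows)
  m <- nrow(posthoc)
  posthoc$p_adj <- 1 - (1 - posthoc$p_raw)^m
  structure(
    list(test = "two-way RM-ANOVA (interaction)", statistic = unname(Fv),
         df = c((a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1)),
         p = unname(p), correction = "sidak", posthoc = posthoc, n = n),
    class = "stat_result"
  )
}

#' Two-tailed paired t-test
#'
#' @param x,y Paired numeric vectors of equal length (>= 2).
#' @return A `stat_result` list with `statistic` (t), `df`, `p`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  st <- paired_t_stat(x, y)
  structure(
    list(test = "paired t", statistic = st[["t"]], df = st[["df"]],
         p = st[["p_raw"]], correction = "none", n = length(x)),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$test, ": statistic = ", signif(x$statistic, 4),
      ", df = (", paste(signif(x$df, 4), collapse = ", "), "), p = ",
      signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Day contrast of log-transformed pauses
#'
#' Natural-log transforms each trial's pause, averages per rat and day, and
#' runs a one-way repeated-measures ANOVA across days. Non-positive pauses
#' (impossible for real pauses, possible for malformed input) are excluded
#' with a warning, as are censored pauses when `exclude_censored` is set.
#'
#' @param pauses Numeric vector of pause durations (s), one per trial.
#' @param rat_id Subject id per trial.
#' @param day Day/session label per trial.
#' @param censored Optional logical per trial; censored pauses are excluded
#'   when `exclude_censored = TRUE` (default).
#' @param exclude_censored Drop censored pauses from the duration statistics.
#' @return A `stat_result` from [one_way_rm_anova()], with the per-rat,
#'   per-day mean log-pause table in `$cell_means`.
#' @export
log_pause_contrast <- function(pauses, rat_id, day, censored = NULL,
                               exclude_censored = TRUE) {
  keep <- rep(TRUE, length(pauses))
  if (!is.null(censored) && exclude_censored) keep <- keep & !censored
  bad <- pauses <= 0
  if (any(bad & keep)) {
    warning(sum(bad & keep), " non-positive pause(s) excluded", call. = FALSE)
  }
  keep <- keep & !bad
  d <- data.frame(lp = log(pauses[keep]), rat = rat_id[keep], day = day[keep])
  agg <- stats::aggregate(lp ~ rat + day, data = d, FUN = mean)
  wide <- stats::reshape(agg, idvar = "rat", timevar = "day",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^lp\\.", "", colnames(mat))
  res <- one_way_rm_anova(mat)
  res$cell_means <- agg
  res
}

#' Correlation of post-distraction pause with evoked activity
#'
#' Pearson correlation between the log-transformed post-distractor pause and
#' the mean evoked response (z-score in the 3 s after the distractor), over
#' distracted trials.
#'
#' @param post_pauses Positive pause durations (s), distracted trials only.
#' @param evoked_means Mean evoked z-score per trial, same length.
#' @return A `stat_result` with `statistic` = Pearson r, `df`, `p`.
#' @export
pause_activity_correlation <- function(post_pauses, evoked_means) {
  if (length(post_pauses) < 3) stop("need at least 3 trials", call. = FALSE)
  if (stats::sd(evoked_means) == 0 || stats::sd(post_pauses) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(log(post_pauses), evoked_means, method = "pearson")
  structure(
    list(test = "Pearson correlation (log pause vs evoked)",
         statistic = unname(ct$estimate), df = unname(ct$parameter),
         p = ct$p.value, correction = "none", n = length(post_pauses)),
    class = "stat_result"
  )
}

# Fig-S1-style stimulus class: white-noise-containing, tone (without white
# noise), or neither (visual-only)
stimulus_class <- function(labels) {
  cls <- ifelse(grepl("white_noise", labels), "white_noise",
                ifelse(grepl("tone", labels), "tone", "other"))
  factor(cls, levels = c("white_noise", "tone", "other"))
}

#' Distractor-type effectiveness contrast
#'
#' Groups trials into three stimulus classes — distractors containing white
#' noise, distractors containing a tone (but no white noise), and the rest —
#' computes each rat's distraction probability per class, and compares the
#' classes with a one-way repeated-measures ANOVA. Rats lacking trials in
#' some class are excluded with a warning.
#'
#' @param trials A trial data.frame with `stimulus_label` and `distracted`.
#' @param rat_id Subject id per trial.
#' @return A `stat_result`, with the per-rat class probabilities in
#'   `$cell_means`.
#' @export
stimulus_type_contrast <- function(trials, rat_id) {
  cls <- stimulus_class(trials$stimulus_label)
  d <- data.frame(rat = rat_id, cls = cls, distracted = trials$distracted)
  agg <- stats::aggregate(distracted ~ rat + cls, data = d, FUN = mean,
                          drop = FALSE)
  wide <- stats::reshape(agg, idvar = "rat", timevar = "cls",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^distracted\\.", "", colnames(mat))
  mat <- mat[, colSums(!is.na(mat)) > 0, drop = FALSE]  # classes never seen
  complete <- stats::complete.cases(mat)
  if (any(!complete)) {
    warning(sum(!complete),
            " rat(s) excluded: no trials in some stimulus class",
            call. = FALSE)
  }
  res <- one_way_rm_anova(mat[complete, , drop = FALSE])
  res$cell_means <- agg
  res
}
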