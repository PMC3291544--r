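#' Median GCR rate with a nonparametric confidence interval
#'
#' Fluctuation-assay rates are heavily skewed (jackpot cultures), so the
#' cohort rate is summarized by the median of the per-culture rate values
#' and a distribution-free confidence interval built from order statistics:
#' the interval `(x_(k), x_(n-k+1))` has exact coverage
#' `1 - 2 * P(Binomial(n, 1/2) <= k - 1)` for the population median.  The
#' narrowest symmetric interval with coverage at least `conf` is reported;
#' when no interval reaches `conf` (small n) the full range is used and the
#' achieved coverage is reported.
#'
#' @param per_culture_rates numeric vector (>= 1 value) of nonnegative
#'   per-culture rate values (events per cell per generation).
#' @param conf target two-sided coverage (default 0.95).
#' @return A `rate_estimate`: list with `median`, `ci_low`, `ci_high`,
#'   `coverage` (achieved), `n`.
#' @export
estimate_gcr_rate <- function(per_culture_rates, conf = 0.95) {
  x <- per_culture_rates
  if (!length(x)) stop("need at least one per-culture rate")
  if (any(x < 0)) stop("per-culture rates must be nonnegative")
  n <- length(x)
  xs <- sort(x)
  cov_k <- function(k) 1 - 2 * stats::pbinom(k - 1, n, 0.5)
  ks <- seq_len(max(1L, floor(n / 2)))
  achieving <- ks[vapply(ks, cov_k, numeric(1)) >= conf]
  k <- if (length(achieving)) max(achieving) else 1L
  structure(list(median = stats::median(xs),
                 ci_low = xs[k], ci_high = xs[n - k + 1L],
                 coverage = cov_k(k), n = n),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(format_rate(x), sprintf("(n = %d, coverage %.1f%%)\n",
                              x$n, 100 * x$coverage))
  invisible(x)
}

# "8.4 [5.9-9.6]e-08" style formatting
format_rate <- function(est) {
  if (est$median == 0) return("0 [0-0]")
  ex <- floor(log10(est$median))
  sc <- 10^ex
  sprintf("%.1f [%.1f-%.1f]e%+03d", est$median / sc, est$ci_low / sc,
          est$ci_high / sc, ex)
}

#' Fold change between two rate estimates
#'
#' Ratio of medians, reported with the rounding convention used for
#' strain-table fold columns: folds below 1 are rounded to one decimal;
#' folds of 1 or more are rounded to the nearest integer and then expressed
#' to two significant figures (so 119.05 prints as 120, 2.62 as 3, 19.05 as
#' 19).  The unrounded value is attached as attribute `raw`.
#'
#' @param test,reference `rate_estimate` objects (or bare medians).
#' @return Rounded fold change (numeric scalar) with attribute `raw`.
#' @export
fold_change <- function(test, reference) {
  t_med <- if (inherits(test, "rate_estimate")) test$median else test
  r_med <- if (inherits(reference, "rate_estimate")) reference$median else reference
  if (r_med <= 0) stop("reference median rate must be > 0")
  raw <- t_med / r_med
  rounded <- if (raw < 1) round(raw, 1) else signif(round(raw), 2)
  structure(rounded, raw = raw)
}

#' Observed per-arm duplication rates
#'
#' The observed duplication rate of a chromosome arm is the strain's total
#' GCR (CanR 5FOAR) rate multiplied by the fraction of analyzed GCRs
#' carrying a duplication of that arm: `r_arm = R_total * n_arm / N`.
#' Arms with zero observed duplications get rate 0 together with an
#' upper-limit annotation: the rate a single hypothetical event would have
#' contributed (`R_total / n_duplications`).
#'
#' @param total_rate the strain's total GCR rate.
#' @param cohort a `cohort_summary` (or a named count vector with attribute
#'   `n` giving the number of GCRs analyzed).
#' @param arms character vector fixing the arm universe (e.g.
#'   `paste0(arm_table(ann)$chrom, "-", arm_table(ann)$arm)`); defaults to
#'   the arms observed in the cohort.
#' @param upper_limit_rule how the upper-limit denominator is chosen:
#'   `"duplications"` (number of duplication-bearing GCRs, default) or
#'   `"all_gcrs"` (all GCRs analyzed).
#' @return An `arm_rate_table` data.frame: `arm`, `count`, `rate`,
#'   `upper_limit` (NA except for zero-count arms), with attributes
#'   `total_rate`, `n`, `n_duplications`.
#' @export
arm_duplication_rates <- function(total_rate, cohort, arms = NULL,
                                  upper_limit_rule = c("duplications",
                                                       "all_gcrs")) {
  upper_limit_rule <- match.arg(upper_limit_rule)
  if (inherits(cohort, "cohort_summary")) {
    counts <- cohort$arm_counts
    n <- cohort$n
    n_dup <- cohort$n_arm_duplication
  } else {
    counts <- cohort
    n <- attr(cohort, "n")
    if (is.null(n)) n <- sum(counts)
    n_dup <- sum(counts)
  }
  if (n <= 0) stop("cohort has no isolates")
  if (is.null(arms)) arms <- names(counts)
  cnt <- integer(length(arms))
  names(cnt) <- arms
  if (length(counts)) cnt[names(counts)] <- as.integer(counts)

  denom <- if (upper_limit_rule == "duplications") max(n_dup, 1L) else n
  ul <- total_rate / denom
  out <- data.frame(arm = arms, count = as.integer(cnt),
                    rate = total_rate * cnt / n,
                    upper_limit = ifelse(cnt == 0L, ul, NA_real_),
                    stringsAsFactors = FALSE)
  attr(out, "total_rate") <- total_rate
  attr(out, "n") <- n
  attr(out, "n_duplications") <- n_dup
  class(out) <- c("arm_rate_table", "data.frame")
  out
}

#' Expected per-arm rates and observed/expected ratios
#'
#' Compares a test strain's per-arm duplication rates against the
#' expectation that the mutation scales every arm's rate uniformly.  The
#' scaling constant `S` is the sum of the test strain's arm duplication
#' rates divided by the sum of the control strain's, and the expected rate
#' of each arm is the control rate times `S`.  Zero-count rules: when the
#' control has no duplications of an arm, its upper-limit rate stands in
#' before scaling; when the test has none, the test upper limit is used as
#' the observed rate if it is below the expectation, otherwise the ratio is
#' set to 1; when both are zero the ratio is 1.
#'
#' Optionally, arms are flagged significant when the observed rate falls
#' outside the interval obtained by scaling the control arm rate by the
#' fold confidence interval of the test strain's bulk rate
#' (`fold_ci = test rate CI / control median rate`).
#'
#' @param control,test `arm_rate_table` objects over the same arm universe.
#' @param fold_ci optional length-2 numeric: the bulk-rate fold CI of the
#'   test strain relative to the control.
#' @return data.frame with one row per arm: counts, observed and expected
#'   rates, `ratio`, `log2_ratio`, and `significant` (NA when `fold_ci` is
#'   not given); attribute `scaling_constant` holds `S`.
#' @export
expected_arm_rates <- function(control, test, fold_ci = NULL) {
  if (!setequal(control$arm, test$arm))
    stop("control and test tables cover different arm universes")
  test <- test[match(control$arm, test$arm), ]
  s_ctrl <- sum(control$rate)
  if (s_ctrl <= 0) stop("control strain has zero total duplication rate")
  S <- sum(test$rate) / s_ctrl

  ctrl_base <- ifelse(control$count == 0L, control$upper_limit, control$rate)
  expected <- ctrl_base * S
  observed <- test$rate
  ratio <- numeric(nrow(control))
  for (i in seq_along(ratio)) {
    if (test$count[i] == 0L && control$count[i] == 0L) {
      ratio[i] <- 1
      observed[i] <- expected[i]
    } else if (test$count[i] == 0L) {
      ul <- test$upper_limit[i]
      if (ul < expected[i]) {
        observed[i] <- ul
        ratio[i] <- ul / expected[i]
      } else {
        ratio[i] <- 1
        observed[i] <- expected[i]
      }
    } else {
      ratio[i] <- observed[i] / expected[i]
    }
  }

  significant <- rep(NA, nrow(control))
  if (!is.null(fold_ci)) {
    lo <- ctrl_base * min(fold_ci)
    hi <- ctrl_base * max(fold_ci)
    significant <- observed < lo | observed > hi
  }

  out <- data.frame(arm = control$arm,
                    control_count = control$count, test_count = test$count,
                    observed_rate = observed, expected_rate = expected,
                    ratio = ratio, log2_ratio = log2(ratio),
                    significant = significant, stringsAsFactors = FALSE)
  attr(out, "scaling_constant") <- S
  out
}

#' Monte Carlo multinomial goodness-of-fit test
#'
#' Tests observed category counts against multinomial probabilities by
#' comparing the Pearson chi-square discrepancy (or the log-likelihood
#' ratio, `statistic = "llr"`) of the observed table with the discrepancies
#' of `replicates` tables drawn from the null multinomial.  The empirical
#' p-value is `(k + 1) / (R + 1)` where `k` is the number of null
#' replicates with a discrepancy at least as large as observed.
#'
#' @param observed_counts integer vector of observed counts.
#' @param probabilities null probabilities (same length, summing to 1).
#' @param replicates number of Monte Carlo replicates (default 2000).
#' @param seed RNG seed.
#' @param statistic `"chisq"` (default) or `"llr"`.
#' @return A `test_result` list: `statistic`, `p_value`, `method`,
#'   `parameters` (replicates, seed, exceedances).
#' @export
mc_multinomial_test <- function(observed_counts, probabilities,
                                replicates = 2000, seed = 1,
                                statistic = c("chisq", "llr")) {
  statistic <- match.arg(statistic)
  if (length(observed_counts) != length(probabilities))
    stop("observed counts and probabilities have different lengths")
  if (abs(sum(probabilities) - 1) > 1e-8)
    stop("probabilities must sum to 1")
  stopifnot(replicates >= 1)
  N <- sum(observed_counts)

  disc <- function(counts) {
    # counts: matrix categories x replicates (or a vector)
    counts <- as.matrix(counts)
    E <- N * probabilities
    if (statistic == "chisq") {
      keep <- E > 0
      out <- colSums((counts[keep, , drop = FALSE] - E[keep])^2 / E[keep])
      extra <- colSums(counts[!keep, , drop = FALSE] > 0) > 0
      out[extra] <- Inf
      out
    } else {
      ratio <- counts / E
      term <- counts * log(ratio)
      term[counts == 0] <- 0
      out <- 2 * colSums(term)
      out[colSums(counts[E == 0, , drop = FALSE] > 0) > 0] <- Inf
      out
    }
  }
  obs_stat <- disc(matrix(observed_counts, ncol = 1))

  k <- with_seed(seed, {
    total <- 0L
    left <- replicates
    chunk <- 50000L
    while (left > 0L) {
      m <- min(left, chunk)
      null <- stats::rmultinom(m, N, probabilities)
      total <- total + sum(disc(null) >= obs_stat - 1e-9)
      left <- left - m
    }
    total
  })
  structure(list(statistic = unname(obs_stat),
                 p_value = (k + 1) / (replicates + 1),
                 method = paste0("Monte Carlo multinomial (", statistic, ")"),
                 parameters = list(replicates = replicates, seed = seed,
                                   exceedances = k)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' One-sided exact binomial overrepresentation test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(N, p_arm)`, computed
#' by direct pmf summation.  Used to ask whether an arm attracted more
#' duplications than its share of catalog targets predicts.
#'
#' @param k observed count; `N` trials; `p_arm` null probability in (0, 1).
#' @return A `test_result`.
#' @export
exact_binomial_overrep <- function(k, N, p_arm) {
  if (p_arm <= 0 || p_arm >= 1) stop("p_arm must be in (0, 1)")
  stopifnot(k >= 0, k <= N)
  p <- if (k == 0) 1 else sum(stats::dbinom(k:N, N, p_arm))
  structure(list(statistic = k, p_value = min(1, p),
                 method = "exact binomial (upper tail)",
                 parameters = list(N = N, p = p_arm)),
            class = "test_result")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A `test_result`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  if (all(rowSums(table) == 0) || all(colSums(table) == 0))
    stop("degenerate table with all-zero margins")
  ft <- stats::fisher.test(table)
  structure(list(statistic = unname(ft$estimate), p_value = ft$p.value,
                 method = "Fisher's exact test (two-sided)",
                 parameters = list(table = table)),
            class = "test_result")
}

#' Exact binomial substitute for McNemar's test
#'
#' Two-sided exact test on the discordant-pair counts of a paired design:
#' `p = min(1, 2 * P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`.
#'
#' @param b,c discordant-pair counts (e.g. aneuploid-only-under-selection
#'   and aneuploid-only-without-selection culture pairs).
#' @return A `test_result`.
#' @export
paired_exact_test <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  if (b == 0 && c == 0) {
    warning("no discordant pairs; p = 1")
    p <- 1
  } else {
    p <- min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
  }
  structure(list(statistic = min(b, c), p_value = p,
                 method = "exact binomial substitute for McNemar's test",
                 parameters = list(b = b, c = c)),
            class = "test_result")
}

#' Upper-tail hypergeometric overlap test
#'
#' `P(X >= k)` for the overlap between a drawn set of size `n` and a
#' reference set of size `K` inside a population of size `M`.
#'
#' @param M population size; `K` reference-set size; `n` draw size;
#'   `k` observed overlap.
#' @return A `test_result`.
#' @export
hypergeom_overlap <- function(M, K, n, k) {
  if (K > M || n > M || k > min(K, n) || k < 0)
    stop("inconsistent hypergeometric parameters")
  p <- if (k == 0) 1 else stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
  structure(list(statistic = k, p_value = p,
                 method = "hypergeometric overlap (upper tail)",
                 parameters = list(M = M, K = K, n = n)),
            class = "test_result")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()]: exact for small samples
#' without ties, normal approximation with tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @return A `test_result`.
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # fully tied degenerate samples
  structure(list(statistic = unname(wt$statistic), p_value = p,
                 method = "Wilcoxon rank-sum test (two-sided)",
                 parameters = list(n_x = length(x), n_y = length(y))),
            class = "test_result")
}

#' Bonferroni-corrected decisions
#'
#' @param p_values numeric vector of p-values.
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `threshold` (`alpha / m`) and logical `reject`.
#' @export
adjust_bonferroni <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  stopifnot(m >= 1)
  thr <- alpha / m
  list(threshold = thr, reject = p_values <= thr)
}
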