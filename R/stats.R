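#' Paired before/after sample
#'
#' @param before,after numeric vectors of equal length (>= 3), finite.
#' @param label metric/electrode tag carried into results.
#' @return an object of class `paired_sample`.
#' @export
paired_sample <- function(before, after, label = "") {
  if (length(before) != length(after)) {
    stop("`before` and `after` must have equal length", call. = FALSE)
  }
  if (length(before) < 3L) {
    stop("need at least 3 pairs", call. = FALSE)
  }
  if (!all(is.finite(before)) || !all(is.finite(after))) {
    stop("values must be finite", call. = FALSE)
  }
  structure(list(before = as.numeric(before), after = as.numeric(after),
                 label = label),
            class = "paired_sample")
}

stat_result <- function(test_name, statistic, p_value, n_effective,
                        alpha = 0.05) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n_effective = n_effective,
                 alpha = alpha, significant = p_value < alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic %.4g, p %.4g (n %d)%s\n",
              x$test_name, x$statistic, x$p_value, x$n_effective,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' `significant` means evidence *against* normality at `alpha`.
#'
#' @param x numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha significance level (default 0.05).
#' @return a `stat_result` with `test_name = "shapiro_wilk"`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  if (length(x) < 3L || length(x) > 5000L) {
    stop("normality_check requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("normality_check is undefined for a constant sequence", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  stat_result("shapiro_wilk", sw$statistic, sw$p.value, length(x), alpha)
}

#' Paired t-test
#'
#' Two-sided Student t on the differences `after - before`.
#'
#' @param sample a [paired_sample()]; the differences must not be constant.
#' @param alpha significance level (default 0.05).
#' @return a `stat_result` with `test_name = "paired_t"`.
#' @export
paired_t <- function(sample, alpha = 0.05) {
  d <- sample$after - sample$before
  if (stats::sd(d) == 0) {
    stop("paired_t is undefined: differences have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(sample$after, sample$before, paired = TRUE)
  stat_result("paired_t", tt$statistic, tt$p.value, length(d), alpha)
}

# Exact null distribution of the positive-rank sum W+ over all 2^n sign
# assignments, as integer counts over doubled ranks (midranks can be
# half-integers). Returns counts[k+1] = #assignments with 2*W+ = k.
signed_rank_counts <- function(ranks2) {
  counts <- 1
  for (r in ranks2) {
    nv <- numeric(length(counts) + r)
    nv[seq_along(counts)] <- counts
    nv[r + seq_along(counts)] <- nv[r + seq_along(counts)] + counts
    counts <- nv
  }
  counts
}

#' Wilcoxon signed-rank test (exact for small samples)
#'
#' Zero differences are dropped (Wilcoxon's original method) and ties
#' mid-ranked; the statistic is the positive-rank sum W+. For an effective n
#' of at most 25 the two-sided p-value is exact over the null distribution of
#' all 2^n sign assignments (two-sided as twice the smaller tail, capped at
#' 1); above 25 a normal approximation with tie and continuity corrections is
#' used.
#'
#' @param sample a [paired_sample()] with at least one nonzero difference.
#' @param alpha significance level (default 0.05).
#' @return a `stat_result` with `test_name = "wilcoxon_signed_rank"`;
#'   `n_effective` counts the nonzero differences.
#' @export
wilcoxon_signed_rank <- function(sample, alpha = 0.05) {
  d <- sample$after - sample$before
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("wilcoxon_signed_rank is undefined: all differences are zero",
         call. = FALSE)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    r2 <- as.integer(round(2 * r))
    counts <- signed_rank_counts(r2)
    total <- 2^n
    k <- as.integer(round(2 * W))
    idx <- seq_along(counts) - 1L
    p_ge <- sum(counts[idx >= k]) / total
    p_le <- sum(counts[idx <= k]) / total
    p <- min(1, 2 * min(p_ge, p_le))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- if (W == mu) 0 else (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  stat_result("wilcoxon_signed_rank", W, p, n, alpha)
}

#' Choose and run the paired test for a metric
#'
#' Under `policy = "paper_fixed"` the test assignment is fixed by metric
#' class: relative-PSD metrics get the paired t-test; absolute-PSD metrics and
#' the MPF/RMS fatigue indices get the Wilcoxon signed-rank test. Under
#' `policy = "normality_gated"` a Shapiro-Wilk check on the differences picks
#' the t-test when normality is not rejected and the Wilcoxon test otherwise.
#'
#' @param sample a [paired_sample()].
#' @param metric metric name (e.g. `"relative_mu"`, `"absolute_mu"`, `"mpf"`).
#' @param policy `"paper_fixed"` or `"normality_gated"`.
#' @param alpha significance level (default 0.05).
#' @return the chosen test's `stat_result`.
#' @export
analyze_metric <- function(sample, metric, policy = c("paper_fixed",
                                                      "normality_gated"),
                           alpha = 0.05) {
  policy <- match.arg(policy)
  use_t <- if (policy == "paper_fixed") {
    grepl("^relative", metric)
  } else {
    d <- sample$after - sample$before
    normality_check(d, alpha)$p_value >= alpha
  }
  if (use_t) paired_t(sample, alpha) else wilcoxon_signed_rank(sample, alpha)
}
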