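#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test on differences `b - a`. Zero differences are
#' discarded (the classical rule), absolute differences are ranked with
#' average ranks for ties, and the test statistic is `W = min(W+, W-)`,
#' the smaller of the positive- and negative-rank sums. With at most 25
#' non-zero differences and no ties in their absolute values the p-value is
#' exact (the null distribution of the signed-rank sum over all `2^n` sign
#' assignments); otherwise a normal approximation with tie correction and a
#' continuity correction is used.
#'
#' @param a numeric scores under condition 1 (e.g. single frames), one per
#'   paired unit.
#' @param b numeric scores under condition 2 (e.g. video snippets), same
#'   order.
#' @param exact_max largest tie-free `n` for which the exact distribution is
#'   used (default 25).
#' @return An object of classes `spr_test` and `htest` with `statistic`
#'   (`W`), `p.value`, `n_effective` (non-zero differences) and `method`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 4, 5, 7, 9))  # p = 0.0625
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25L) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b))
    stop("paired samples differ in length", call. = FALSE)
  if (length(a) < 1L) stop("empty paired sample", call. = FALSE)
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("test undefined: all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    # exact two-sided p over the 2^n equally likely sign assignments:
    # P(W+ <= w) + P(W+ >= M - w), symmetric null
    p <- min(1, 2 * stats::psignrank(w, n))
    method <- "exact"
  } else {
    mn <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mn + 0.5) / sqrt(sigma2)  # continuity correction toward mean
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal-approximation"
  }
  p <- max(p, .Machine$double.xmin)
  structure(list(statistic = c(W = w), p.value = p,
                 n_effective = n, method =
                   paste("Wilcoxon signed-rank test,", method),
                 data.name = "paired differences b - a"),
            class = c("spr_test", "htest"))
}

#' Bonferroni correction
#'
#' Divides the significance threshold by the number of simultaneous tests;
#' a test rejects iff its p-value is strictly below `alpha / m`.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @param alpha family-wise significance level in `(0, 1)` (default 0.05).
#' @return A list with `threshold` (`alpha / m`), `m`, `alpha` and `reject`
#'   (logical vector aligned with `p_values`; `NA` p-values yield `NA`).
#' @examples
#' bonferroni(c(0.01, 0.04, 0.2))  # threshold 0.0167; only the first rejects
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L)
    stop("no p-values to correct", call. = FALSE)
  if (!(alpha > 0 && alpha < 1))
    stop("alpha must be in (0, 1)", call. = FALSE)
  ok <- !is.na(p_values)
  if (any(p_values[ok] <= 0 | p_values[ok] > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(p_values)
  threshold <- alpha / m
  list(threshold = threshold, m = m, alpha = alpha,
       reject = ifelse(is.na(p_values), NA, p_values < threshold))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-aware: both vectors are converted to average ranks and rho is their
#' Pearson correlation. The two-sided p-value uses the t approximation with
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `>= 3`, neither constant.
#' @return An object of classes `spr_test` and `htest` with `statistic`
#'   (`rho`), `p.value` and `n_effective`.
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))  # rho = 0.8
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("rank correlation undefined: constant input", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- max(2 * stats::pt(-abs(tval), df = n - 2), .Machine$double.xmin)
  }
  structure(list(statistic = c(rho = rho), p.value = p,
                 n_effective = n,
                 method = "Spearman rank correlation (t approximation)",
                 data.name = "x and y"),
            class = c("spr_test", "htest"))
}
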