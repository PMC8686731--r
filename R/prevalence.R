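# Per-taxon diet description and sex comparison: exact binomial prevalence
# intervals, two-sided Fisher tests with Holm-Bonferroni control, diet
# richness with Mann-Whitney tests, and BCa bootstrap intervals.

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval obtained by inverting the two-sided exact binomial test,
#' computed through the Beta-quantile formulation:
#' `lo = qbeta(alpha/2, k, n-k+1)`, `hi = qbeta(1-alpha/2, k+1, n-k)`, with
#' `lo = 0` when `k = 0` and `hi = 1` when `k = n`.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param alpha Two-sided error level (default 0.05 for a 95% interval).
#' @return Numeric `c(lo, hi)` at full precision.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (n < 1 || k < 0 || k > n)
    pd_validation_error("need 0 <= k <= n with n >= 1")
  if (alpha <= 0 || alpha >= 1) pd_validation_error("alpha must be in (0,1)")
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo = lo, hi = hi)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins and sums hypergeometric point probabilities of
#' all tables whose probability does not exceed that of the observed table
#' (the minimum-likelihood rule used by mainstream statistical software).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value in \[0, 1\]; tables with a zero margin carry no
#'   information and return 1 with a warning.
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == 2) || any(tb < 0) || any(tb != round(tb)))
    pd_validation_error("need a 2x2 table of non-negative integers")
  r1 <- sum(tb[1, ]); c1 <- sum(tb[, 1]); n <- sum(tb)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warning("table has a zero margin; p = 1", call. = FALSE)
    return(1)
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tb[1, 1], c1, n - c1, r1)
  # tolerance guards against ties broken by floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values (monotone, capped at 1) in the input order.
#' @export
holm_bonferroni <- function(pvals) {
  if (any(pvals < 0 | pvals > 1)) pd_validation_error("p-values must be in [0,1]")
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  o <- order(pvals)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * pvals[o]))
  adj[order(o)]
}

#' Per-taxon prevalence table with sex comparison
#'
#' Builds a Table-1-style summary: per-taxon detection counts, prevalences
#' and Clopper-Pearson intervals overall and per sex, a two-sided Fisher
#' test of the female/male split, and Holm-Bonferroni adjusted p-values over
#' the reported taxa.
#'
#' Denominators default to the analyzed specimens (the columns of `pm`), but
#' can be overridden with the collected sample sizes when prevalence should
#' be expressed per collected individual; both conventions are meaningful
#' and the one used is recorded in the output.
#'
#' @param pm A [presence_matrix()] (or 0/1 matrix with a `sex` attribute).
#' @param denominators Optional `c(overall, female, male)` sample sizes; the
#'   default uses the analyzed columns of `pm`.
#' @param top Keep only this many taxa (by overall prevalence, ties broken
#'   by taxon name) before Fisher/Holm; `NULL` keeps all.
#' @param alpha CI level parameter (default 0.05).
#' @return Data.frame with one row per taxon, ordered by decreasing overall
#'   prevalence; attribute `denominators` records the convention used.
#' @export
prevalence_table <- function(pm, denominators = NULL, top = NULL,
                             alpha = 0.05) {
  sex <- attr(pm, "sex")
  if (is.null(sex)) pd_validation_error("pm must carry a sex attribute")
  f <- sex == "female"
  k_f <- rowSums(pm[, f, drop = FALSE])
  k_m <- rowSums(pm[, !f, drop = FALSE])
  k_all <- k_f + k_m
  den <- denominators %||% c(ncol(pm), sum(f), sum(!f))
  if (any(den < 1)) pd_validation_error("denominators must be >= 1")
  ord <- order(-k_all, rownames(pm))
  idx <- if (is.null(top)) ord else utils::head(ord, top)
  ci <- function(k, n) t(vapply(k, clopper_pearson, c(lo = 0, hi = 0),
                                n = n, alpha = alpha))
  ci_all <- ci(k_all[idx], den[1])
  ci_f <- ci(k_f[idx], den[2])
  ci_m <- ci(k_m[idx], den[3])
  fisher_p <- vapply(idx, function(i) {
    suppressWarnings(fisher_exact_2x2(matrix(
      c(k_f[i], den[2] - k_f[i], k_m[i], den[3] - k_m[i]), 2,
      byrow = TRUE)))
  }, 0)
  out <- data.frame(
    taxon = rownames(pm)[idx],
    k_overall = k_all[idx], n_overall = den[1],
    k_female = k_f[idx], n_female = den[2],
    k_male = k_m[idx], n_male = den[3],
    prevalence = k_all[idx] / den[1],
    ci_lo = ci_all[, 1], ci_hi = ci_all[, 2],
    prevalence_female = k_f[idx] / den[2],
    ci_lo_female = ci_f[, 1], ci_hi_female = ci_f[, 2],
    prevalence_male = k_m[idx] / den[3],
    ci_lo_male = ci_m[, 1], ci_hi_male = ci_m[, 2],
    fisher_p = fisher_p,
    holm_p = holm_bonferroni(fisher_p),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "denominators") <- den
  out
}

#' Aggregate presence to taxonomic orders
#'
#' A specimen counts as positive for an order if at least one member taxon
#' is present. Orders are looked up from the cleaned table's taxonomy.
#'
#' @param pm A [presence_matrix()].
#' @param orders Character vector mapping each row of `pm` to its order
#'   label (empty/NA rows are grouped as `"unresolved"`).
#' @return A [presence_matrix()] with one row per order.
#' @export
order_presence <- function(pm, orders) {
  if (length(orders) != nrow(pm))
    pd_validation_error("orders must have one entry per taxon row")
  orders[is.na(orders) | !nzchar(orders)] <- "unresolved"
  agg <- rowsum(unwrap(pm), orders)
  suppressMessages(presence_matrix((agg > 0) * 1L, attr(pm, "sex")))
}

#' Pairwise Clopper-Pearson CI overlap flags
#'
#' The informal order-level comparison: two prevalences are called
#' distinguishable when their CIs do not overlap.
#'
#' @param lo,hi Equal-length vectors of interval bounds (named or not).
#' @return Logical symmetric matrix; `TRUE` where intervals overlap.
#' @export
ci_overlap_matrix <- function(lo, hi) {
  n <- length(lo)
  out <- matrix(TRUE, n, n, dimnames = list(names(lo), names(lo)))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- lo[i] <= hi[j] & lo[j] <= hi[i]
  out
}

#' Per-specimen diet richness
#'
#' @param pm A [presence_matrix()].
#' @return Named integer vector of per-specimen taxon counts.
#' @export
richness_per_sample <- function(pm) colSums(unwrap(pm))

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-sided test using the tie-corrected normal approximation without
#' continuity correction (richness data are heavily tied); `method =
#' "exact"` enumerates all group assignments of the pooled values instead
#' (feasible for small samples, used for validation).
#'
#' @param x,y Numeric samples.
#' @param method `"normal"` (default) or `"exact"`.
#' @return List with `U` (statistic for `x`), `Z` (0 for the exact method's
#'   degenerate-variance case), and two-sided `p`.
#' @export
mann_whitney <- function(x, y, method = c("normal", "exact")) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y); nn <- n1 + n2
  if (n1 == 0 || n2 == 0) pd_validation_error("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (method == "exact") {
    combs <- utils::combn(nn, n1)
    us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(U = u, Z = NA_real_, p = p))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sigma2 <= 0) return(list(U = u, Z = 0, p = 1))
  z <- (u - mu) / sqrt(sigma2)
  list(U = u, Z = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}

# Shared BCa interval machinery: observed statistic, bootstrap replicates,
# jackknife replicates.
bca_interval <- function(t0, t_boot, t_jack, alpha) {
  if (length(unique(t_boot)) == 1 && t_boot[1] == t0)
    return(c(lo = t0, hi = t0))
  b <- mean(t_boot < t0) + 0.5 * mean(t_boot == t0)
  if (b <= 0 || b >= 1)  # all mass on one side: fall back to percentile
    return(stats::setNames(
      stats::quantile(t_boot, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                      type = 7), c("lo", "hi")))
  z0 <- stats::qnorm(b)
  d <- mean(t_jack) - t_jack
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  stats::setNames(stats::quantile(t_boot, adj, names = FALSE, type = 7),
                  c("lo", "hi"))
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Bias correction `z0` comes from the bootstrap distribution's position
#' relative to the observed statistic; acceleration `a` from the jackknife
#' skewness. Constant input returns a zero-width interval.
#'
#' @param values Numeric vector (length >= 2).
#' @param statistic Function of a numeric vector (default [mean()]).
#' @param B Number of bootstrap resamples (default 2000).
#' @param alpha Two-sided error level.
#' @param seed Optional seed for reproducibility.
#' @return `c(lo, hi)`.
#' @export
bca_bootstrap_ci <- function(values, statistic = mean, B = 2000,
                             alpha = 0.05, seed = NULL) {
  n <- length(values)
  if (n < 2) pd_validation_error("need at least 2 values")
  t0 <- statistic(values)
  if (length(unique(values)) == 1) return(c(lo = t0, hi = t0))
  t_boot <- with_seed(seed, vapply(seq_len(B), function(i)
    statistic(values[sample.int(n, n, replace = TRUE)]), 0))
  t_jack <- vapply(seq_len(n), function(i) statistic(values[-i]), 0)
  bca_interval(t0, t_boot, t_jack, alpha)
}

#' Format a proportion the way diet tables print it
#'
#' Three decimals with trailing zeros trimmed (`0.49`, not `0.490`).
#'
#' @param x Numeric vector in \[0, 1\].
#' @return Character vector.
#' @export
format_prevalence <- function(x) {
  out <- formatC(round(x, 3), format = "f", digits = 3)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}
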