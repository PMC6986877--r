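#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test with fixed margins, computed from hypergeometric
#' point probabilities in log space so that very unbalanced tables (counts in
#' the thousands) remain accurate. The default two-sided rule sums all point
#' probabilities not exceeding the observed one (within relative tolerance
#' 1e-7), the convention used by `stats::fisher.test`; the doubling rule
#' (twice the smaller tail, capped at 1) is available as an option.
#'
#' @param a,b,c,d non-negative integer counts; row 1 is `(a, b)`, row 2 is
#'   `(c, d)`. `a` is the count whose upper tail the `"greater"` alternative
#'   addresses.
#' @param sided `"two_sided"`, `"greater"` or `"less"`.
#' @param method two-sided rule: `"minlike"` (default) or `"doubling"`.
#' @return p-value in `[0, 1]`.
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)          # 34/70
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             sided = c("two_sided", "greater", "less"),
                             method = c("minlike", "doubling")) {
  sided <- match.arg(sided)
  method <- match.arg(method)
  cnt <- c(a, b, c, d)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("table entries must be non-negative integers")
  if (sum(cnt) == 0) stop("at least one margin must be positive")
  m <- a + b   # row-1 total
  n <- c + d   # row-2 total
  k <- a + c   # column-1 total
  p_greater <- stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
  p_less <- stats::phyper(a, m, n, k)
  if (sided == "greater") return(p_greater)
  if (sided == "less") return(p_less)
  if (method == "doubling") return(min(1, 2 * min(p_greater, p_less)))
  lo <- max(0, k - n)
  hi <- min(k, m)
  ld <- stats::dhyper(lo:hi, m, n, k, log = TRUE)
  lobs <- stats::dhyper(a, m, n, k, log = TRUE)
  min(1, sum(exp(ld[ld <= lobs + log1p(1e-7)])))
}

#' One- or two-sided two-proportion z-test
#'
#' Pooled-variance z-test for the difference of two binomial proportions, with
#' optional Yates continuity correction: `0.5 * (1/n1 + 1/n2)` is subtracted
#' from the absolute difference (floored at 0) before standardising.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @param sided `"greater"` tests `p1 > p2`; `"less"` tests `p1 < p2`.
#' @param continuity apply the continuity correction (default `TRUE`).
#' @return p-value.
#' @examples
#' two_proportion_test(9, 10, 1, 10, "greater")   # ~8.7e-4
#' @export
two_proportion_test <- function(x1, n1, x2, n2,
                                sided = c("greater", "less", "two_sided"),
                                continuity = TRUE) {
  sided <- match.arg(sided)
  if (n1 <= 0 || n2 <= 0) stop("trial counts must be positive")
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2)
    stop("successes must lie in [0, trials]")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  d <- p1 - p2
  if (continuity) {
    cc <- 0.5 * (1 / n1 + 1 / n2)
    d <- sign(d) * max(0, abs(d) - cc)
  }
  if (se == 0) return(1)
  z <- d / se
  switch(sided,
         greater = stats::pnorm(z, lower.tail = FALSE),
         less = stats::pnorm(z),
         two_sided = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration for tie-free samples up to a combined n of 50,
#' otherwise the normal approximation with mid-ranks for ties, tie-corrected
#' variance and continuity correction, as implemented by
#' `stats::wilcox.test`.
#'
#' @param x,y non-empty numeric samples.
#' @param sided `"two_sided"`, `"greater"` (x tends larger) or `"less"`.
#' @return p-value.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              sided = c("two_sided", "greater", "less")) {
  sided <- match.arg(sided)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- (length(x) + length(y) <= 50) && !anyDuplicated(c(x, y))
  alt <- switch(sided, two_sided = "two.sided", greater = "greater",
                less = "less")
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = TRUE)$p.value)
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up FDR adjustment; order is preserved relative to the input.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# Newton inversion of the trigamma function, used when moment-matching the
# scaled inverse-chi-square prior of the moderated t.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits a scaled inverse-chi-square prior (`d0` degrees of freedom, scale
#' `s0_sq`) to a set of sample variances by moment matching of the log
#' variances through digamma/trigamma identities. When the observed spread of
#' log variances is no larger than expected from sampling alone, `d0` is
#' infinite and every variance shrinks fully to `s0_sq`.
#'
#' @param s2 per-region sample variances (pooled across the two groups).
#' @param df residual degrees of freedom for each variance.
#' @return List with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_variance_prior <- function(s2, df) {
  stopifnot(length(s2) == length(df) || length(df) == 1)
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 1e-15 & df > 0
  if (sum(ok) < 2) stop("need at least 2 positive variances to fit the prior")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  n <- length(e)
  cvar <- mean((e - emean)^2 * n / (n - 1) - trigamma(df[ok] / 2))
  if (cvar > 0) {
    d0 <- 2 * trigamma_inverse(cvar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    message("log-variance spread consistent with pure sampling noise; ",
            "treating prior degrees of freedom as infinite")
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated t-statistics for two groups
#'
#' For each region the pooled sample variance `s_g^2` (with `d_g = n1 + n2 - 2`
#' degrees of freedom) is shrunk toward a prior variance:
#' `s~^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`, and the moderated
#' statistic `t~ = (mean1 - mean2) / (s~ * sqrt(1/n1 + 1/n2))` is referred to
#' a t distribution on `d0 + d_g` degrees of freedom. With `d0 = 0` this is
#' the ordinary pooled-variance two-sample t-test; with `d0 = Inf` it is a
#' z-like test at the prior variance.
#'
#' @param group1,group2 numeric matrices, regions in rows and replicates in
#'   columns (at least 2 columns each).
#' @param prior `"estimate"` (fit via [estimate_variance_prior()]) or a list
#'   with elements `d0` and `s0_sq`.
#' @return data.frame with columns `mean1`, `mean2`, `diff`, `t`, `df`, `p`
#'   (two-sided), one row per region.
#' @export
moderated_t <- function(group1, group2, prior = "estimate") {
  group1 <- as.matrix(group1)
  group2 <- as.matrix(group2)
  if (nrow(group1) != nrow(group2))
    stop("groups must cover the same regions")
  n1 <- ncol(group1)
  n2 <- ncol(group2)
  if (n1 < 2 || n2 < 2) {
    deficit <- if (n1 < 2) "group1" else "group2"
    stop("fewer than 2 replicates in ", deficit,
         "; variance cannot be estimated")
  }
  m1 <- rowMeans(group1)
  m2 <- rowMeans(group2)
  v1 <- apply(group1, 1, stats::var)
  v2 <- apply(group2, 1, stats::var)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  if (identical(prior, "estimate")) prior <- estimate_variance_prior(s2, dg)
  d0 <- prior$d0
  s0 <- prior$s0_sq
  if (is.null(d0) || is.null(s0) || s0 <= 0 || d0 < 0)
    stop("prior must supply d0 >= 0 and s0_sq > 0")
  stilde2 <- if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + dg * s2) / (d0 + dg)
  se <- sqrt(stilde2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  dftot <- d0 + dg
  p <- if (is.infinite(dftot)) 2 * stats::pnorm(-abs(tt)) else
    2 * stats::pt(-abs(tt), dftot)
  data.frame(mean1 = m1, mean2 = m2, diff = m1 - m2, t = tt,
             df = rep(dftot, length(tt)), p = p,
             row.names = rownames(group1))
}

#' qPCR fold enrichment by the delta-delta-Ct method
#'
#' `2^-[(Ct_IP,target - Ct_input,target) - (Ct_IP,control - Ct_input,control)]`:
#' relative enrichment of a target region over a control region after input
#' normalisation. Ct values may be vectors (elementwise result).
#'
#' @param ct_ip_target,ct_input_target cycle thresholds at the target region.
#' @param ct_ip_control,ct_input_control cycle thresholds at the control
#'   region.
#' @return Fold enrichment (positive real).
#' @examples
#' ddct_enrichment(20, 24, 25, 26)  # 8
#' @export
ddct_enrichment <- function(ct_ip_target, ct_input_target,
                            ct_ip_control, ct_input_control) {
  ct <- c(ct_ip_target, ct_input_target, ct_ip_control, ct_input_control)
  if (any(!is.finite(ct))) stop("all Ct values must be finite")
  ddct <- (ct_ip_target - ct_input_target) - (ct_ip_control - ct_input_control)
  2^(-ddct)
}
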