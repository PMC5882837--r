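#' MAX/MIN ratio of replicate expressions
#'
#' The intra-group variability statistic: largest over smallest normalized
#' expression among a group's replicates. If the smallest value is 0 the
#' ratio is `Inf` (such rows are normally removed beforehand by the
#' expression filter).
#'
#' @param values Non-negative replicate expressions, at least one positive.
#' @return `max(values) / min(values)` (>= 1, possibly `Inf`).
#' @export
#' @examples
#' maxmin(c(10, 20, 40, 80, 160, 20))  # 16
maxmin <- function(values) {
  if (any(values < 0) || all(values == 0))
    stop_cfg("'values' must be non-negative with at least one positive")
  max(values) / min(values)
}

#' Coefficient of variation of replicate expressions
#'
#' Sample (n - 1 denominator) standard deviation divided by the mean.
#'
#' @param values Replicate expressions with positive mean.
#' @return CV (dimensionless, >= 0).
#' @export
#' @examples
#' cv(c(10, 20, 40, 80, 160, 20))  # 1.0397
cv <- function(values) {
  m <- mean(values)
  if (m <= 0) stop_cfg("'values' must have positive mean")
  sd(values) / m
}

#' Expression relative to the group mean
#'
#' Each replicate's normalized value divided by the group mean, so the
#' output always averages to 1; the representation used to display cluster
#' co-variation across replicates.
#'
#' @param x A normalized [mir_counts()].
#' @param mirna miRNA name.
#' @param group Group label.
#' @return Numeric vector, one ratio per replicate.
#' @export
relative_expression <- function(x, mirna, group) {
  norm <- normalized_or_stop(x)
  if (!mirna %in% rownames(norm)) stop_cfg("unknown miRNA: ", mirna)
  v <- norm[mirna, group_columns(x, group)]
  m <- mean(v)
  if (m <= 0) stop_cfg("zero group mean for ", mirna, " in ", group)
  v / m
}

#' Per-miRNA, per-group variability table
#'
#' Computes MAX/MIN and CV for every expressed miRNA in every group
#' (each group over its own expressed set, as in per-group profiling).
#'
#' @param x A normalized [mir_counts()].
#' @param threshold Mean-expression filter passed to
#'   [expression_filter()].
#' @return An object of class `variability_table`: data.frame with columns
#'   `mirna`, `group`, `maxmin`, `cv`, `zero_min` (flag for infinite
#'   ratios), carrying the expressed sets as attribute `expressed`.
#' @export
variability_table <- function(x, threshold = 10) {
  norm <- normalized_or_stop(x)
  expressed <- expression_filter(x, threshold)
  rows <- lapply(levels(x$groups), function(g) {
    j <- group_columns(x, g)
    mirs <- expressed[[g]]
    if (!length(mirs)) return(NULL)
    sub <- norm[mirs, j, drop = FALSE]
    data.frame(
      mirna = mirs, group = g,
      maxmin = apply(sub, 1L, maxmin),
      cv = apply(sub, 1L, cv),
      zero_min = apply(sub, 1L, function(v) min(v) == 0),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "expressed") <- expressed
  class(out) <- c("variability_table", "data.frame")
  out
}

#' Hypervariability screen
#'
#' Flags a miRNA as hypervariable in a group iff its MAX/MIN strictly
#' exceeds a threshold of `mean + 2 * SD` of the MAX/MIN distribution. By
#' default one threshold is derived from the reference (control) group and
#' applied to every group; per-group thresholds are available instead.
#'
#' @param vtab A [variability_table()].
#' @param reference_group Group whose MAX/MIN distribution sets the
#'   threshold (default: first group in the table).
#' @param per_group If `TRUE`, each group is screened against its own
#'   `mean + 2 * SD` instead of the reference-group threshold.
#' @return List with `threshold` (named per group), `flags` (data.frame
#'   `mirna`, `group`, `maxmin`, `hypervariable`) and `summary`
#'   (data.frame per group: `n_expressed`, `maxmin_mean`, `maxmin_sd`,
#'   `maxmin_mean_plus_2sd`, `cv_mean`, `cv_sd`, `n_hypervariable`,
#'   `pct_hypervariable` — percentage reported to one decimal).
#' @export
hypervariability_screen <- function(vtab, reference_group = NULL,
                                    per_group = FALSE) {
  stopifnot(inherits(vtab, "variability_table"))
  groups <- unique(vtab$group)
  reference_group <- reference_group %||% groups[1]
  if (!reference_group %in% groups)
    stop_cfg("reference group absent: ", reference_group)

  # rows with a zero replicate have MAX/MIN = Inf: they are flagged
  # unconditionally but excluded from the mean/SD defining the threshold
  per_group_stats <- lapply(groups, function(g) {
    mm <- vtab$maxmin[vtab$group == g]
    cvs <- vtab$cv[vtab$group == g]
    fin <- mm[is.finite(mm)]
    c(n = length(mm), mean = mean(fin), sd = sd(fin),
      thr = mean(fin) + 2 * sd(fin), cv_mean = mean(cvs), cv_sd = sd(cvs))
  })
  names(per_group_stats) <- groups

  thr <- if (per_group)
    vapply(per_group_stats, `[[`, numeric(1), "thr")
  else setNames(rep(per_group_stats[[reference_group]][["thr"]],
                    length(groups)), groups)

  flags <- vtab[, c("mirna", "group", "maxmin")]
  flags$hypervariable <- flags$maxmin > thr[flags$group]

  summary <- do.call(rbind, lapply(groups, function(g) {
    st <- per_group_stats[[g]]
    n_hyper <- sum(flags$hypervariable[flags$group == g])
    data.frame(
      group = g, n_expressed = as.integer(st[["n"]]),
      maxmin_mean = st[["mean"]], maxmin_sd = st[["sd"]],
      maxmin_mean_plus_2sd = st[["thr"]],
      cv_mean = st[["cv_mean"]], cv_sd = st[["cv_sd"]],
      threshold_used = thr[[g]],
      n_hypervariable = n_hyper,
      pct_hypervariable = round(100 * n_hyper / st[["n"]], 1L),
      stringsAsFactors = FALSE
    )
  }))
  list(threshold = thr, flags = flags, summary = summary,
       reference_group = reference_group)
}

#' Co-variation score of a miRNA set within a group
#'
#' Mean pairwise Pearson correlation of the members' relative-expression
#' vectors across the group's replicates. This is an artifact-defined
#' statistic quantifying the co-variation that cluster-encoded miRNAs
#' display across profiles. Zero-variance members yield undefined
#' correlations; such pairs are skipped and counted.
#'
#' @param x A normalized [mir_counts()].
#' @param mirnas At least two miRNA names.
#' @param group Group label.
#' @return List: `score` (mean pairwise r, in `[-1, 1]`), `n_pairs` (pairs
#'   entering the mean) and `n_skipped` (zero-variance pairs).
#' @export
covariation_score <- function(x, mirnas, group) {
  if (length(mirnas) < 2L) stop_cfg("need at least two miRNAs")
  rel <- vapply(mirnas, function(m) relative_expression(x, m, group),
                numeric(length(group_columns(x, group))))
  pairs <- combn(length(mirnas), 2L)
  rs <- apply(pairs, 2L, function(ij) {
    a <- rel[, ij[1]]; b <- rel[, ij[2]]
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  })
  list(score = mean(rs, na.rm = TRUE),
       n_pairs = sum(!is.na(rs)),
       n_skipped = sum(is.na(rs)))
}
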