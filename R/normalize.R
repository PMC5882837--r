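#' Median-of-ratios size factors
#'
#' The DESeq-procedure scaling: the factor of library `j` is the median
#' over miRNAs of `k_ij / geomean_i`, where `geomean_i` is the geometric
#' mean of miRNA `i` across libraries. Rows containing any zero count have
#' no finite geometric-mean log and are excluded from the median. The
#' geometric mean of the factors is not constrained to 1.
#'
#' @param counts Non-negative count matrix (miRNAs x libraries) or a
#'   [mir_counts()].
#' @return Numeric vector of positive size factors, one per column.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), 3,
#'             dimnames = list(paste0("m", 1:3), c("a", "b")))
#' size_factors(m)  # 1/sqrt(2), sqrt(2)
size_factors <- function(counts) {
  if (inherits(counts, "mir_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  logs <- log(counts)
  loggeo <- rowMeans(logs)
  use <- is.finite(loggeo)
  if (!any(use))
    stop_cfg("no miRNA with all-positive counts; size factors undefined")
  # median of the ratios themselves; reference implementations that take
  # the median on the log scale differ for even row counts (geometric vs
  # arithmetic interpolation between the two middle ratios)
  ratios <- exp(logs[use, , drop = FALSE] - loggeo[use])
  s <- apply(ratios, 2L, median)
  if (any(s <= 0) || any(!is.finite(s)))
    stop_cfg("non-positive size factor computed")
  s
}

#' Normalize a count matrix by median-of-ratios size factors
#'
#' @param x A [mir_counts()].
#' @param scope `"global"` computes one set of size factors across all
#'   libraries (used for between-group comparisons); `"group"` normalizes
#'   each group's libraries among themselves (used for within-group
#'   variability screening).
#' @return `x` with `size_factors` and `normalized` (`counts / size
#'   factor`, raw counts retained) filled in.
#' @export
normalize_counts <- function(x, scope = c("global", "group")) {
  stopifnot(inherits(x, "mir_counts"))
  scope <- match.arg(scope)
  s <- if (scope == "global") size_factors(x$counts)
  else {
    out <- numeric(ncol(x$counts))
    for (g in levels(x$groups)) {
      j <- group_columns(x, g)
      out[j] <- size_factors(x$counts[, j, drop = FALSE])
    }
    out
  }
  names(s) <- colnames(x$counts)
  x$size_factors <- s
  x$normalized <- sweep(x$counts, 2L, s, `/`)
  x$scope <- scope
  x
}

#' Mean-expression filter
#'
#' A miRNA counts as expressed in a group iff the mean of its normalized
#' values across the group's replicates is at least `threshold` (closed
#' boundary: a mean of exactly `threshold` is kept).
#'
#' @param x A normalized [mir_counts()].
#' @param threshold Mean normalized expression cut-off (default 10 reads).
#' @return Named list (one element per group) of expressed miRNA name
#'   vectors.
#' @export
expression_filter <- function(x, threshold = 10) {
  norm <- normalized_or_stop(x)
  out <- lapply(levels(x$groups), function(g) {
    j <- group_columns(x, g)
    rownames(norm)[rowMeans(norm[, j, drop = FALSE]) >= threshold]
  })
  setNames(out, levels(x$groups))
}

#' Tested set for a two-group comparison
#'
#' The miRNAs entered into differential testing between two groups: by
#' default the union of the two groups' expressed sets (the most inclusive
#' choice), optionally their intersection.
#'
#' @param x A normalized [mir_counts()].
#' @param group_a,group_b The two group labels.
#' @param threshold Passed to [expression_filter()].
#' @param mode `"union"` (default) or `"intersection"`.
#' @return Character vector of miRNA names, in count-matrix row order.
#' @export
tested_set <- function(x, group_a, group_b, threshold = 10,
                       mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  expressed <- expression_filter(x, threshold)
  if (!all(c(group_a, group_b) %in% names(expressed)))
    stop_cfg("unknown group label")
  set <- if (mode == "union")
    union(expressed[[group_a]], expressed[[group_b]])
  else intersect(expressed[[group_a]], expressed[[group_b]])
  rownames(x$counts)[rownames(x$counts) %in% set]
}
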