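#' Construct a miRNA count matrix with group annotations
#'
#' Lightweight container in the DGEList style: an integer matrix of raw
#' counts (rows = mature miRNAs, columns = libraries) plus a per-column
#' group factor; size factors and normalized values are attached by
#' [normalize_counts()].
#'
#' @param counts Non-negative integer matrix with row and column names.
#' @param groups Factor or character vector, one group label per column.
#' @return An object of class `mir_counts`: list with elements `counts`,
#'   `groups`, and (once computed) `size_factors`, `normalized`.
#' @export
#' @examples
#' m <- matrix(rpois(40, 50), 10, 4,
#'             dimnames = list(paste0("miR-", 1:10), paste0("lib", 1:4)))
#' x <- mir_counts(m, rep(c("A", "B"), each = 2))
mir_counts <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_cfg("'counts' needs row (miRNA) and column (library) names")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_cfg("'counts' must be non-negative integers")
  storage.mode(counts) <- "integer"
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop_cfg("'groups' must have one label per column")
  structure(list(counts = counts, groups = groups,
                 size_factors = NULL, normalized = NULL),
            class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat("mir_counts:", nrow(x$counts), "miRNAs x", ncol(x$counts),
      "libraries;", nlevels(x$groups), "groups (",
      paste(levels(x$groups), collapse = ", "), ")\n")
  cat("  normalized:", !is.null(x$normalized), "\n")
  invisible(x)
}

#' @export
dim.mir_counts <- function(x) dim(x$counts)

group_columns <- function(x, group) {
  if (!group %in% levels(x$groups))
    stop_cfg("unknown group label: ", group)
  which(x$groups == group)
}

normalized_or_stop <- function(x) {
  if (is.null(x$normalized))
    stop_cfg("normalized values not computed; call normalize_counts() first")
  x$normalized
}

#' Write / read a count matrix as TSV with a two-line header
#'
#' Line 1 holds library labels, line 2 the group label of each library;
#' subsequent rows are `miRNA<TAB>count...`. Normalized values are not
#' stored; recompute them after reading.
#'
#' @param x A `mir_counts`.
#' @param path Output (input) TSV path.
#' @return `write_counts()`: invisibly `path`; `read_counts()`: a
#'   `mir_counts`.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "mir_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("library", colnames(x$counts)), collapse = "\t"), con)
  writeLines(paste(c("group", as.character(x$groups)), collapse = "\t"), con)
  write.table(x$counts, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  hdr <- readLines(path, n = 2L)
  libs <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][-1]
  groups <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]][-1]
  body <- read.delim(path, skip = 2L, header = FALSE,
                     stringsAsFactors = FALSE)
  counts <- as.matrix(body[, -1, drop = FALSE])
  dimnames(counts) <- list(body[[1]], libs)
  mir_counts(counts, groups)
}
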