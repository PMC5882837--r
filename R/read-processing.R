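#' Demultiplex a multiplexed read batch by 3'-adapter barcode
#'
#' Each library's 3' adapter starts with a distinct 11-nt barcode; a read
#' belongs to the library whose barcode occurs first (leftmost exact match)
#' in its sequence. Reads matching no barcode go to the `undetermined`
#' bin, so the output is a partition of the input.
#'
#' @param batch A `read_batch` (see [read_fastq()]).
#' @param barcodes Named character vector of pairwise-distinct 11-nt
#'   barcodes (names = library labels).
#' @return Named list of `read_batch` objects, one per library, plus
#'   `undetermined`.
#' @export
demultiplex <- function(batch, barcodes) {
  check_barcodes(barcodes)
  if (is.null(names(barcodes)) || anyDuplicated(names(barcodes)))
    stop_cfg("'barcodes' must be uniquely named by library")
  pos <- vapply(barcodes,
                function(b) regexpr(b, batch$sequence, fixed = TRUE),
                integer(nrow(batch)))
  pos <- matrix(pos, nrow = nrow(batch))
  pos[pos < 0L] <- NA_integer_
  hit <- rep(NA_integer_, nrow(batch))
  has <- rowSums(!is.na(pos)) > 0L
  if (any(has))
    hit[has] <- apply(pos[has, , drop = FALSE], 1L, which.min)
  out <- lapply(seq_along(barcodes), function(j)
    batch[!is.na(hit) & hit == j, , drop = FALSE])
  names(out) <- names(barcodes)
  out$undetermined <- batch[is.na(hit), , drop = FALSE]
  out
}

#' Trim the 3' adapter from read sequences
#'
#' Cuts each read at the leftmost exact occurrence of the adapter prefix
#' (first `min(10, nchar(adapter3))` nt). Reads without a match are
#' returned unchanged and flagged untrimmed rather than discarded.
#'
#' @param sequences Character vector of read sequences.
#' @param adapter3 The library's full 3'-adapter sequence (barcode + common
#'   tail), >= 8 nt.
#' @return data.frame with columns `insert` and `trimmed` (logical).
#' @export
#' @examples
#' trim_adapter(c("ACGTACGTTGGAATTCTC", "ACGTACGT"), "TGGAATTCTCGG")
trim_adapter <- function(sequences, adapter3) {
  if (nchar(adapter3) < 8) stop_cfg("'adapter3' must be >= 8 nt")
  k <- min(10L, nchar(adapter3))
  probe <- substr(adapter3, 1L, k)
  pos <- regexpr(probe, sequences, fixed = TRUE)
  trimmed <- pos > 0L
  insert <- ifelse(trimmed, substr(sequences, 1L, pos - 1L), sequences)
  data.frame(insert = insert, trimmed = trimmed, stringsAsFactors = FALSE)
}

#' Length-filter and collapse trimmed inserts
#'
#' Discards inserts shorter than `min_len` and collapses survivors into
#' unique sequences with multiplicities.
#'
#' @param inserts Character vector of trimmed insert sequences.
#' @param min_len Minimum insert length kept; the default 16 follows the
#'   16-36 nt small-RNA window used in the emulated protocol (see the
#'   methods vignette for the 15/16/18-nt discussion).
#' @return Named integer vector: unique sequence -> multiplicity. The sum
#'   equals the number of surviving reads.
#' @export
#' @examples
#' filter_and_collapse(c("ACGT", strrep("ACGTA", 5), strrep("ACGTA", 5)))
filter_and_collapse <- function(inserts, min_len = 16L) {
  keep <- inserts[nchar(inserts) >= min_len]
  if (!length(keep)) return(setNames(integer(0), character(0)))
  tab <- table(keep)
  setNames(as.integer(tab), names(tab))
}

#' Quantify collapsed sequences against a mature-miRNA reference
#'
#' A unique sequence contributes its multiplicity to a mature miRNA iff it
#' matches the mature sequence exactly or is a 3'-end variant of it
#' shortened or extended by at most 2 nt (isomiR tolerance). Sequences
#' matching no mature are tallied as unassigned; a sequence matching two
#' matures (impossible for references from [make_reference()]) is an
#' error.
#'
#' @param collapsed Named integer vector from [filter_and_collapse()].
#' @param reference A `mir_reference`.
#' @return List: `counts` (named integer vector over all mature strands)
#'   and `unassigned` (total multiplicity of unmatched sequences).
#' @export
quantify <- function(collapsed, reference) {
  stopifnot(inherits(reference, "mir_reference"))
  mt <- mature_table(reference)
  if (anyDuplicated(mt$sequence))
    stop_cfg("reference mature sequences are not unique")
  counts <- setNames(integer(nrow(mt)), mt$mature)
  if (!length(collapsed))
    return(list(counts = counts, unassigned = 0L))

  # core = mature minus its last 2 nt; a read matches iff some core is its
  # prefix and its length is within +/-2 of that mature's length. The
  # hash maps each core to every mature sharing it, so two matures with
  # one core are caught as ambiguous rather than silently merged.
  core <- substr(mt$sequence, 1L, nchar(mt$sequence) - 2L)
  core_lens <- sort(unique(nchar(core)))
  lookup <- new.env(parent = emptyenv(), size = nrow(mt))
  for (i in seq_len(nrow(mt)))
    assign(core[i], c(get0(core[i], envir = lookup), i), envir = lookup)

  useq <- names(collapsed)
  ulen <- nchar(useq)
  unassigned <- 0L
  for (s in seq_along(useq)) {
    hits <- integer(0)
    for (l in core_lens) {
      if (ulen[s] < l) next
      i <- get0(substr(useq[s], 1L, l), envir = lookup)
      if (!is.null(i))
        hits <- c(hits, i[abs(ulen[s] - nchar(mt$sequence[i])) <= 2L])
    }
    if (length(hits) > 1L)
      stop_cfg("ambiguous assignment: sequence matches ",
               paste(mt$mature[hits], collapse = ", "))
    if (length(hits) == 1L)
      counts[hits] <- counts[hits] + collapsed[[s]]
    else unassigned <- unassigned + collapsed[[s]]
  }
  list(counts = counts, unassigned = unassigned)
}

#' Run the full read-processing chain on a multiplexed batch
#'
#' demultiplex -> trim -> length-filter -> collapse -> quantify, with
#' stage-by-stage read accounting per library.
#'
#' @param batch A `read_batch` (from [read_fastq()] or
#'   [simulate_reads()]).
#' @param reference A `mir_reference`.
#' @param barcodes Named 11-nt barcodes (default: the batch's `barcodes`
#'   attribute).
#' @param adapter3 Common adapter tail following the barcode (default: the
#'   batch's `adapter3` attribute).
#' @param min_len Minimum insert length (see [filter_and_collapse()]).
#' @return List: `counts` (a [mir_counts()]; one column per library, all
#'   libraries assigned the group `"unassigned"` until the caller sets a
#'   design), `unassigned` (per-library multiplicity of unmatched
#'   sequences), `accounting` (data.frame: library, reads_in, trimmed,
#'   passed_filter, assigned, unassigned).
#' @export
process_reads <- function(batch, reference,
                          barcodes = attr(batch, "barcodes"),
                          adapter3 = attr(batch, "adapter3"),
                          min_len = 16L) {
  if (is.null(barcodes) || is.null(adapter3))
    stop_cfg("'barcodes' and 'adapter3' are required")
  bins <- demultiplex(batch, barcodes)
  libs <- names(barcodes)
  mt <- mature_table(reference)
  counts <- matrix(0L, nrow(mt), length(libs),
                   dimnames = list(mt$mature, libs))
  unassigned <- setNames(integer(length(libs)), libs)
  acct <- data.frame(library = libs, reads_in = 0L, trimmed = 0L,
                     passed_filter = 0L, assigned = 0L, unassigned = 0L,
                     stringsAsFactors = FALSE)
  for (j in seq_along(libs)) {
    lib <- libs[j]
    reads <- bins[[lib]]
    acct$reads_in[j] <- nrow(reads)
    tr <- trim_adapter(reads$sequence, paste0(barcodes[[lib]], adapter3))
    acct$trimmed[j] <- sum(tr$trimmed)
    collapsed <- filter_and_collapse(tr$insert[tr$trimmed], min_len)
    acct$passed_filter[j] <- sum(collapsed)
    q <- quantify(collapsed, reference)
    counts[, j] <- q$counts
    unassigned[j] <- q$unassigned
    acct$assigned[j] <- sum(q$counts)
    acct$unassigned[j] <- q$unassigned
  }
  list(counts = mir_counts(counts, rep("unassigned", length(libs))),
       unassigned = unassigned,
       n_undetermined = nrow(bins$undetermined),
       accounting = acct)
}
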