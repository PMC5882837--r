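#' Generate a synthetic mature-miRNA reference
#'
#' Builds hairpin precursors, their mature -5p/-3p products (mutual
#' "partner" strands) and a cluster partition. Mature sequences are random
#' 20-24 nt DNA strings whose first 18 nt are pairwise distinct, which
#' guarantees that exact-match quantification with a +/- 2-nt 3'-end
#' tolerance can never assign one read to two matures.
#'
#' @param config A [sim_config()].
#' @return An object of class `mir_reference`: a list with
#'   `hairpins` (data.frame: `hairpin_id`, `cluster_id`, `name_5p`,
#'   `name_3p`, `seq_5p`, `seq_3p`; `NA` where an arm is absent) and
#'   `clusters` (named list mapping cluster id to ordered hairpin ids).
#' @export
#' @examples
#' ref <- make_reference(sim_config(n_hairpins = 3, seed = 1))
#' nrow(ref$hairpins)
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_hairpins
  with_seed(config$seed, {
    hp_id <- sprintf("hp-%03d", seq_len(n))
    cluster_id <- hp_id  # singleton partition by default
    for (cl in names(config$clusters))
      cluster_id[config$clusters[[cl]]] <- cl

    # distinct 18-nt prefixes, then random 3' tails to total length 20-24
    prefixes <- character(0)
    while (length(prefixes) < 2L * n)
      prefixes <- unique(c(prefixes, random_dna(2L * n, 18L)))
    prefixes <- prefixes[seq_len(2L * n)]
    lens <- sample(20:24, 2L * n, replace = TRUE)
    seqs <- paste0(prefixes, random_dna(2L * n, lens - 18L))

    arms <- matrix(TRUE, n, 2L)
    if (config$p_single_arm > 0) {
      single <- runif(n) < config$p_single_arm
      drop3p <- runif(n) < 0.5
      arms[single & drop3p, 2L] <- FALSE
      arms[single & !drop3p, 1L] <- FALSE
    }

    hairpins <- data.frame(
      hairpin_id = hp_id,
      cluster_id = cluster_id,
      name_5p = ifelse(arms[, 1L], paste0(hp_id, "-5p"), NA_character_),
      name_3p = ifelse(arms[, 2L], paste0(hp_id, "-3p"), NA_character_),
      seq_5p = ifelse(arms[, 1L], seqs[seq_len(n)], NA_character_),
      seq_3p = ifelse(arms[, 2L], seqs[n + seq_len(n)], NA_character_),
      stringsAsFactors = FALSE
    )
    clusters <- split(hp_id, cluster_id)
    clusters <- clusters[unique(cluster_id)]  # keep declaration order
    structure(list(hairpins = hairpins, clusters = clusters),
              class = "mir_reference")
  })
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

#' Mature-strand annotation table of a reference
#'
#' @param reference A `mir_reference`.
#' @return data.frame with one row per mature strand: `mature`,
#'   `hairpin_id`, `cluster_id`, `arm` ("5p"/"3p"), `sequence`, `partner`
#'   (name of the opposite-arm strand, `NA` if the hairpin emits one arm).
#' @export
mature_table <- function(reference) {
  stopifnot(inherits(reference, "mir_reference"))
  hp <- reference$hairpins
  long <- rbind(
    data.frame(mature = hp$name_5p, hairpin_id = hp$hairpin_id,
               cluster_id = hp$cluster_id, arm = "5p",
               sequence = hp$seq_5p, partner = hp$name_3p,
               stringsAsFactors = FALSE),
    data.frame(mature = hp$name_3p, hairpin_id = hp$hairpin_id,
               cluster_id = hp$cluster_id, arm = "3p",
               sequence = hp$seq_3p, partner = hp$name_5p,
               stringsAsFactors = FALSE)
  )
  long <- long[!is.na(long$mature), , drop = FALSE]
  long[order(long$hairpin_id, long$arm), , drop = FALSE]
}

#' @export
print.mir_reference <- function(x, ...) {
  mt <- mature_table(x)
  cat("mir_reference:", nrow(x$hairpins), "hairpins,", nrow(mt),
      "mature strands,", length(x$clusters), "clusters\n")
  invisible(x)
}

#' Write a reference as mature FASTA plus annotation sidecar
#'
#' @param reference A `mir_reference`.
#' @param fasta,sidecar Output paths (mature sequences as FASTA; TSV with
#'   columns mature, hairpin_id, cluster_id, arm).
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(reference, fasta, sidecar) {
  mt <- mature_table(reference)
  set <- Biostrings::DNAStringSet(setNames(mt$sequence, mt$mature))
  Biostrings::writeXStringSet(set, fasta)
  write.table(mt[, c("mature", "hairpin_id", "cluster_id", "arm")],
              sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, sidecar = sidecar))
}

#' Read a reference back from FASTA + sidecar
#'
#' @param fasta,sidecar Paths written by [write_reference()].
#' @return A `mir_reference`.
#' @export
read_reference <- function(fasta, sidecar) {
  set <- Biostrings::readDNAStringSet(fasta)
  ann <- read.delim(sidecar, stringsAsFactors = FALSE)
  stopifnot(all(ann$mature %in% names(set)))
  ann$sequence <- as.character(set[ann$mature])
  wide <- split(ann, ann$hairpin_id)
  hairpins <- do.call(rbind, lapply(wide, function(d) {
    p5 <- d[d$arm == "5p", , drop = FALSE]
    p3 <- d[d$arm == "3p", , drop = FALSE]
    data.frame(
      hairpin_id = d$hairpin_id[1], cluster_id = d$cluster_id[1],
      name_5p = if (nrow(p5)) p5$mature else NA_character_,
      name_3p = if (nrow(p3)) p3$mature else NA_character_,
      seq_5p = if (nrow(p5)) p5$sequence else NA_character_,
      seq_3p = if (nrow(p3)) p3$sequence else NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  hairpins <- hairpins[order(hairpins$hairpin_id), , drop = FALSE]
  rownames(hairpins) <- NULL
  clusters <- split(hairpins$hairpin_id, hairpins$cluster_id)
  structure(list(hairpins = hairpins, clusters = clusters),
            class = "mir_reference")
}
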