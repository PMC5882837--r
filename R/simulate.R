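#' Simulate a miRNA count matrix
#'
#' Draws counts under the generative model the downstream statistics
#' assume. The expectation of strand `i` in library `j` (group `g`) is
#' `baseline_i * depth_j * cluster_factor_{c(i),j} * effect_{i,g}`, where
#' the cluster factor is one lognormal draw shared by every strand of a
#' hypervariable cluster within a library (producing their co-variation),
#' and a planted effect multiplies the named strand by `fce` and its
#' partner strand by `fce^partner_attenuation` in the affected groups.
#' Counts are negative binomial with `Var = mu + alpha_i * mu^2`, where
#' the per-strand dispersion `alpha_i` is one lognormal draw around the
#' configured median (`dispersion_log_sd = 0` gives a common dispersion);
#' with `dispersion = 0` the generator returns the noise-free limit
#' `round(mu)`.
#'
#' @param reference A [make_reference()] result.
#' @param config The [sim_config()] used to build it.
#' @return A [mir_counts()] with library columns `lib01`, `lib02`, ... in
#'   group-blocked order.
#' @export
#' @examples
#' cfg <- sim_config(n_hairpins = 20, seed = 3)
#' x <- simulate_counts(make_reference(cfg), cfg)
simulate_counts <- function(reference, config) {
  stopifnot(inherits(reference, "mir_reference"),
            inherits(config, "sim_config"))
  mt <- mature_table(reference)
  n_lib <- config$n_groups * config$n_replicates
  libs <- sprintf("lib%02d", seq_len(n_lib))
  groups <- rep(config$group_labels, each = config$n_replicates)

  if (!is.null(config$planted_effects)) {
    unknown <- setdiff(config$planted_effects$mature, mt$mature)
    if (length(unknown))
      stop_cfg("planted effect names unknown mature strand(s): ",
               paste(unknown, collapse = ", "))
  }

  with_seed(config$seed + 1L, {
    baseline <- rlnorm(nrow(mt), config$log_mean, config$log_sd)
    if (!is.null(config$effect_min_baseline) &&
        !is.null(config$planted_effects)) {
      eff_strands <- config$planted_effects$mature
      eff_strands <- unique(c(eff_strands,
                              mt$partner[match(eff_strands, mt$mature)]))
      i <- match(eff_strands[!is.na(eff_strands)], mt$mature)
      baseline[i] <- pmax(baseline[i], config$effect_min_baseline)
    }
    alpha <- if (config$dispersion_log_sd > 0)
      config$dispersion * rlnorm(nrow(mt), 0, config$dispersion_log_sd)
    else rep(config$dispersion, nrow(mt))
    mu <- outer(baseline, config$depth_factors)
    dimnames(mu) <- list(mt$mature, libs)

    for (cl in names(config$hypervariable_log_sd)) {
      members <- mt$cluster_id == cl
      if (!any(members)) next
      fac <- rlnorm(n_lib, 0, config$hypervariable_log_sd[[cl]])
      mu[members, ] <- sweep(mu[members, , drop = FALSE], 2L, fac, `*`)
    }

    if (!is.null(config$planted_effects)) {
      for (k in seq_len(nrow(config$planted_effects))) {
        eff <- config$planted_effects[k, ]
        cols <- groups %in% strsplit(eff$groups, ";", fixed = TRUE)[[1]]
        mu[eff$mature, cols] <- mu[eff$mature, cols] * eff$fce
        partner <- mt$partner[mt$mature == eff$mature]
        if (!is.na(partner) && eff$partner_attenuation > 0)
          mu[partner, cols] <- mu[partner, cols] *
            eff$fce^eff$partner_attenuation
      }
    }

    counts <- if (config$dispersion == 0) round(mu)
      else matrix(rnbinom(length(mu), mu = mu,
                          size = rep(1 / alpha, ncol(mu))),
                  nrow(mu), dimnames = dimnames(mu))
    mir_counts(counts, groups)
  })
}

#' Simulate multiplexed small-RNA reads from a count matrix
#'
#' Each count cell contributes that many reads of the form
#' `mature sequence + library barcode + common 3'-adapter tail` with a
#' constant quality line (`"I"` per base; quality is never used
#' downstream). A `junk_fraction` of additional reads carries short
#' (5-14 nt) random inserts to exercise the length filter. All libraries
#' are pooled into one multiplexed batch, as sequenced.
#'
#' @param counts A [mir_counts()].
#' @param reference The matching `mir_reference`.
#' @param config The [sim_config()]; supplies `adapter3`, `barcodes`
#'   (defaulting to [default_barcodes()]), `junk_fraction` and the seed.
#' @return A `read_batch`: data.frame (`read_id`, `sequence`, `quality`)
#'   with attributes `barcodes` (named by library) and `adapter3`.
#' @export
simulate_reads <- function(counts, reference, config) {
  stopifnot(inherits(counts, "mir_counts"),
            inherits(reference, "mir_reference"),
            inherits(config, "sim_config"))
  mt <- mature_table(reference)
  libs <- colnames(counts$counts)
  barcodes <- config$barcodes %||% default_barcodes(length(libs))
  check_barcodes(barcodes, length(libs))
  names(barcodes) <- libs
  seqs <- setNames(mt$sequence, mt$mature)
  if (!all(rownames(counts$counts) %in% names(seqs)))
    stop_cfg("count matrix rows missing from the reference")

  with_seed(config$seed + 2L, {
    per_lib <- lapply(seq_along(libs), function(j) {
      k <- counts$counts[, j]
      insert <- rep(seqs[rownames(counts$counts)], k)
      if (config$junk_fraction > 0) {
        n_junk <- round(config$junk_fraction * length(insert))
        if (n_junk > 0)
          insert <- c(insert, random_dna(n_junk, sample(5:14, n_junk,
                                                        replace = TRUE)))
      }
      data.frame(
        read_id = sprintf("%s_%06d", libs[j], seq_along(insert)),
        sequence = paste0(insert, barcodes[j], config$adapter3),
        stringsAsFactors = FALSE
      )
    })
    batch <- do.call(rbind, per_lib)
    batch$quality <- strrep("I", nchar(batch$sequence))
    rownames(batch) <- NULL
    structure(batch, barcodes = barcodes, adapter3 = config$adapter3,
              class = c("read_batch", "data.frame"))
  })
}

#' Write / read a 4-line FASTQ file
#'
#' @param batch A `read_batch` (data.frame with `read_id`, `sequence`,
#'   `quality`).
#' @param path FASTQ path (".gz" handled transparently).
#' @return `write_fastq()`: invisibly `path`; `read_fastq()`: a
#'   `read_batch`.
#' @export
write_fastq <- function(batch, path) {
  qual <- Biostrings::PhredQuality(batch$quality)
  set <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(batch$sequence, batch$read_id)), qual)
  Biostrings::writeQualityScaledXStringSet(set, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  structure(
    data.frame(read_id = names(set),
               sequence = as.character(set),
               quality = as.character(S4Vectors::mcols(set)$qualities),
               stringsAsFactors = FALSE),
    class = c("read_batch", "data.frame")
  )
}
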