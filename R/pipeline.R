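#' Demonstration configuration mimicking the four-diet-group study design
#'
#' A [sim_config()] with the package defaults (4 groups x 6 replicates,
#' 250 hairpins) plus: three hypervariable clusters of 3, 2 and 3 hairpins
#' (shared-factor log-sd 1), mirroring the three sensory-organ miR gene
#' clusters whose strands co-vary across profiles; six planted perinatal
#' effects (both HF-perinatal groups) with FCEs spanning 0.4-4.8 on
#' two-armed singleton hairpins; and one co-transcribed cluster mate of
#' the strongest effect planted at FCE 3.3, emulating a linked hairpin
#' transcribed as one RNA unit with its neighbour.
#'
#' @param seed RNG seed.
#' @param partner_attenuation Exponent applied to partner strands of
#'   planted effects (1 = perfect arm concordance; 0 = partner unaffected).
#' @param fces The six planted fold-changes.
#' @return A `sim_config`.
#' @export
demo_config <- function(seed = 1L, partner_attenuation = 1,
                        fces = c(0.4, 0.4, 0.45, 2.5, 3.3, 4.8)) {
  stopifnot(length(fces) == 6L)
  clusters <- list("cl-A" = 1:3, "cl-B" = 4:5, "cl-C" = 6:8)
  base <- sim_config(clusters = clusters,
                     hypervariable_log_sd = c("cl-A" = 1, "cl-B" = 1,
                                              "cl-C" = 1),
                     seed = seed)
  ref <- make_reference(base)
  hp <- ref$hairpins
  # singleton hairpins with both arms, outside the hypervariable block
  ok <- which(!is.na(hp$name_5p) & !is.na(hp$name_3p) &
                hp$hairpin_id == hp$cluster_id)
  ok <- ok[ok > 8L]
  if (length(ok) < 7L) stop_cfg("not enough two-armed hairpins")
  planted <- ok[1:6]
  mate <- ok[7L]
  effects <- data.frame(
    mature = c(hp$name_5p[planted], hp$name_3p[mate]),
    groups = "HF-C;HF-HF",
    fce = c(fces, 3.3),
    partner_attenuation = partner_attenuation,
    stringsAsFactors = FALSE
  )
  sim_config(clusters = c(clusters,
                          list("cl-D" = c(planted[6L], mate))),
             hypervariable_log_sd = c("cl-A" = 1, "cl-B" = 1, "cl-C" = 1),
             planted_effects = effects,
             effect_min_baseline = 300,
             seed = seed)
}

#' Run the full analysis pipeline
#'
#' Orchestrates (optionally) simulation and read processing, then
#' normalization, variability screening, all differential comparisons
#' against the reference group, and partner-strand/repeated-impact
#' concordance. Variability is screened on within-group normalization
#' (each group's six profiles normalized among themselves); differential
#' testing uses one global normalization of all libraries, matching the
#' two normalization scopes of the emulated workflow.
#'
#' @param config A [sim_config()].
#' @param reference Optional pre-built `mir_reference` (default:
#'   [make_reference()] from `config`).
#' @param counts Optional [mir_counts()] (default: simulated from
#'   `config`).
#' @param from_reads If `TRUE`, raw reads are simulated and pushed through
#'   the read-processing chain instead of using the count matrix directly.
#' @param test,threshold,alpha_primary,alpha_secondary Passed to
#'   [de_table()].
#' @param reference_group Control group for the hypervariability threshold
#'   and as DE reference (default: first group label).
#' @param repeated_groups The two treatment groups entering
#'   [repeated_impact()] (default: the last two non-reference groups, the
#'   perinatally challenged ones under the default design).
#' @return A result bundle (class `mirnome_run`): list with elements
#'   `reference`, `counts` (globally normalized), `expressed`,
#'   `variability`, `screen`, `covariation`, `de` (named list per
#'   comparison), `pairs`, `confirmed`, `cotranscription`, `repeated`,
#'   `summary` (flat named list) and `log` (character).
#' @export
run_pipeline <- function(config, reference = NULL, counts = NULL,
                         from_reads = FALSE, test = "nb", threshold = 10,
                         alpha_primary = 1e-2, alpha_secondary = 5e-2,
                         reference_group = NULL, repeated_groups = NULL) {
  log <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    log <<- c(log, line)
  }
  stopifnot(inherits(config, "sim_config"))
  reference_group <- reference_group %||% config$group_labels[1L]

  reference <- reference %||% make_reference(config)
  note("reference: ", nrow(reference$hairpins), " hairpins, ",
       nrow(mature_table(reference)), " mature strands")

  if (is.null(counts)) {
    counts <- simulate_counts(reference, config)
    note("simulated counts: ", nrow(counts$counts), " x ",
         ncol(counts$counts))
    if (from_reads) {
      batch <- simulate_reads(counts, reference, config)
      note("simulated reads: ", nrow(batch))
      proc <- process_reads(batch, reference)
      counts <- proc$counts
      counts$groups <- factor(rep(config$group_labels,
                                  each = config$n_replicates))
      note("processed reads; undetermined: ", proc$n_undetermined)
    }
  }

  group_norm <- normalize_counts(counts, scope = "group")
  global_norm <- normalize_counts(counts, scope = "global")
  note("normalized (group + global scope)")

  expressed <- expression_filter(global_norm, threshold)
  vtab <- variability_table(group_norm, threshold)
  screen <- hypervariability_screen(vtab, reference_group)
  note("variability screen: threshold ",
       round(screen$threshold[[reference_group]], 2), " from ",
       reference_group)

  covariation <- list()
  mt <- mature_table(reference)
  for (cl in names(config$hypervariable_log_sd)) {
    members <- mt$mature[mt$cluster_id == cl]
    members <- members[members %in% expressed[[reference_group]]]
    if (length(members) >= 2L)
      covariation[[cl]] <-
        covariation_score(group_norm, members, reference_group)$score
  }

  trt_groups <- setdiff(config$group_labels, reference_group)
  de <- list(); pairs <- list(); confirmed <- list(); cotx <- list()
  dispersions <- estimate_dispersions(global_norm)
  for (g in trt_groups) {
    d <- de_table(global_norm, reference_group, g, test = test,
                  threshold = threshold, alpha_primary = alpha_primary,
                  alpha_secondary = alpha_secondary,
                  dispersions = dispersions)
    de[[g]] <- d
    pairs[[g]] <- pair_partners(d, reference)
    confirmed[[g]] <- confirm_by_partner(pairs[[g]], alpha_secondary)
    cotx[[g]] <- cotranscription_check(d, reference)
    note("DE ", g, " vs ", reference_group, ": m = ", attr(d, "m"),
         ", tier-1 = ", sum(d$tier == 1L, na.rm = TRUE))
  }

  repeated <- NULL
  if (length(trt_groups) >= 2L) {
    repeated_groups <- repeated_groups %||% utils::tail(trt_groups, 2L)
    repeated <- repeated_impact(de[[repeated_groups[1L]]],
                                de[[repeated_groups[2L]]],
                                confirmed[[repeated_groups[1L]]],
                                reference, alpha_secondary)
    note("repeated impact (", paste(repeated_groups, collapse = " & "),
         "): ", length(repeated$members), " member(s)")
  }

  summary <- c(
    setNames(lapply(expressed, length),
             paste0("n_expressed_", names(expressed))),
    setNames(as.list(screen$summary$n_hypervariable),
             paste0("n_hypervariable_", screen$summary$group)),
    setNames(as.list(screen$summary$pct_hypervariable),
             paste0("pct_hypervariable_", screen$summary$group)),
    list(hypervariability_threshold =
           unname(screen$threshold[[reference_group]])),
    setNames(lapply(de, function(d) sum(d$tier == 1L, na.rm = TRUE)),
             paste0("n_tier1_", names(de))),
    setNames(lapply(de, function(d) sum(!is.na(d$tier))),
             paste0("n_tier2_", names(de))),
    setNames(lapply(pairs, function(p)
      if (nrow(p$pairs) >= 3L)
        r_squared(p$pairs$fce, p$pairs$partner_fce) else NA_real_),
      paste0("partner_r2_", names(pairs))),
    if (!is.null(repeated))
      list(repeated_members = repeated$members,
           repeated_r2 = repeated$r_squared)
  )

  structure(list(reference = reference, counts = global_norm,
                 group_normalized = group_norm, expressed = expressed,
                 variability = vtab, screen = screen,
                 covariation = covariation, de = de, pairs = pairs,
                 confirmed = confirmed, cotranscription = cotx,
                 repeated = repeated, summary = summary, log = log,
                 reference_group = reference_group),
            class = "mirnome_run")
}

#' @export
print.mirnome_run <- function(x, ...) {
  cat("mirnome_run (reference group ", x$reference_group, ")\n", sep = "")
  cat("  expressed per group:",
      paste(names(x$expressed), vapply(x$expressed, length, 1L),
            sep = "=", collapse = ", "), "\n")
  for (g in names(x$de))
    cat("  ", g, " vs ", x$reference_group, ": tier-1 = ",
        sum(x$de[[g]]$tier == 1L, na.rm = TRUE), "\n", sep = "")
  if (!is.null(x$repeated))
    cat("  repeated-impact members:", length(x$repeated$members), "\n")
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Emits the per-stage TSVs (counts, size factors, variability summary and
#' scatter data, DE/volcano tables, partner pairs, repeated-impact table),
#' the run log, and a machine-readable JSON summary.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(run, dir) {
  stopifnot(inherits(run, "mirnome_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  out <- function(name) { p <- file.path(dir, name); paths <<- c(paths, p); p }
  tsv <- function(d, name) write.table(d, out(name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)

  write_counts(run$counts, out("counts.tsv"))
  tsv(data.frame(library = names(run$counts$size_factors),
                 size_factor = run$counts$size_factors),
      "size_factors.tsv")
  tsv(run$screen$summary, "variability_summary.tsv")
  tsv(run$variability, "variability_scatter.tsv")
  flagged <- run$screen$flags[run$screen$flags$hypervariable, , drop = FALSE]
  tsv(flagged, "hypervariable_mirnas.tsv")
  for (g in names(run$de)) {
    tag <- gsub("[^A-Za-z0-9]+", "_", g)
    tsv(as.data.frame(run$de[[g]]), paste0("de_", tag, ".tsv"))
    tsv(volcano_data(run$de[[g]]), paste0("volcano_", tag, ".tsv"))
    tsv(run$pairs[[g]]$pairs, paste0("partner_pairs_", tag, ".tsv"))
  }
  if (!is.null(run$repeated))
    tsv(run$repeated$table, "repeated_impact.tsv")
  writeLines(run$log, out("run_log.txt"))
  jsonlite::write_json(run$summary, out("summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
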