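#' Pair significant miRNAs with their partner strands
#'
#' For every tier-1 miRNA of a DE table whose opposite-arm partner strand
#' is itself in the tested set, one row pairing the two strands' FCE and
#' padj values; tier-1 miRNAs whose hairpin emits no second strand, or
#' whose partner is not expressed, are listed separately.
#'
#' @param de A [de_table()] result.
#' @param reference The `mir_reference` providing hairpin links.
#' @return An object of class `partner_pairs`: list with `pairs`
#'   (data.frame `mirna`, `fce`, `padj`, `partner`, `partner_fce`,
#'   `partner_padj`, `hairpin_id`) and `partnerless` (character vector).
#' @export
pair_partners <- function(de, reference) {
  stopifnot(inherits(de, "de_result"), inherits(reference, "mir_reference"))
  mt <- mature_table(reference)
  sig <- de[!is.na(de$tier) & de$tier == 1L, , drop = FALSE]
  missing_ref <- setdiff(sig$mirna, mt$mature)
  if (length(missing_ref))
    stop_cfg("miRNA(s) absent from the reference: ",
             paste(missing_ref, collapse = ", "))
  idx <- match(sig$mirna, mt$mature)
  partner <- mt$partner[idx]
  in_tested <- !is.na(partner) & partner %in% de$mirna
  pairs <- data.frame(
    mirna = sig$mirna[in_tested],
    fce = sig$fce[in_tested],
    padj = sig$padj[in_tested],
    partner = partner[in_tested],
    partner_fce = de$fce[match(partner[in_tested], de$mirna)],
    partner_padj = de$padj[match(partner[in_tested], de$mirna)],
    hairpin_id = mt$hairpin_id[idx][in_tested],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(pairs = pairs, partnerless = sig$mirna[!in_tested],
                 alpha_primary = attr(de, "alpha_primary")),
            class = "partner_pairs")
}

#' @export
print.partner_pairs <- function(x, ...) {
  cat("partner_pairs:", nrow(x$pairs), "paired tier-1 miRNAs,",
      length(x$partnerless), "without an expressed partner\n")
  if (nrow(x$pairs) >= 3L)
    cat("  FCE concordance R^2 =",
        round(r_squared(x$pairs$fce, x$pairs$partner_fce), 2), "\n")
  invisible(x)
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return R-squared in `[0, 1]`, or `NA` (with a warning) when either
#'   argument has zero variance.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 3, 2))  # 0.25
r_squared <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_cfg("'x' and 'y' must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; R-squared undefined")
    return(NA_real_)
  }
  cor(x, y)^2
}

#' Confirm DE calls by partner-strand significance
#'
#' A tier-1 miRNA is confirmed when its partner strand's padj falls below
#' the secondary threshold (strict `<`), i.e. both arms of the hairpin
#' respond.
#'
#' @param pairs A [pair_partners()] result.
#' @param alpha_secondary Secondary padj threshold (default 5.0E-2).
#' @return The confirmed subset of `pairs$pairs` (same columns), one row
#'   per confirmed hairpin.
#' @export
confirm_by_partner <- function(pairs, alpha_secondary = 5e-2) {
  stopifnot(inherits(pairs, "partner_pairs"))
  pairs$pairs[pairs$pairs$partner_padj < alpha_secondary, , drop = FALSE]
}

#' Co-transcription consistency report
#'
#' For each pair of tested miRNAs annotated to the same cluster (miR genes
#' potentially transcribed as one RNA unit, including the two arms of one
#' hairpin) with at least one tier-1 member, reports both FCEs and padj
#' values and whether the FCEs fall on the same side of 1.
#'
#' @param de A [de_table()] result.
#' @param reference The `mir_reference` with cluster annotations.
#' @return data.frame: `cluster_id`, `mirna_a`, `fce_a`, `padj_a`,
#'   `mirna_b`, `fce_b`, `padj_b`, `same_direction`.
#' @export
cotranscription_check <- function(de, reference) {
  stopifnot(inherits(de, "de_result"), inherits(reference, "mir_reference"))
  mt <- mature_table(reference)
  mt <- mt[mt$mature %in% de$mirna, , drop = FALSE]
  tier1 <- de$mirna[!is.na(de$tier) & de$tier == 1L]
  rows <- list()
  for (cl in unique(mt$cluster_id)) {
    members <- mt$mature[mt$cluster_id == cl]
    if (length(members) < 2L || !any(members %in% tier1)) next
    prs <- combn(members, 2L)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1L, k]; b <- prs[2L, k]
      if (!a %in% tier1 && !b %in% tier1) next
      fa <- de$fce[match(a, de$mirna)]; fb <- de$fce[match(b, de$mirna)]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cl, mirna_a = a, fce_a = fa,
        padj_a = de$padj[match(a, de$mirna)],
        mirna_b = b, fce_b = fb,
        padj_b = de$padj[match(b, de$mirna)],
        same_direction = (fa - 1) * (fb - 1) > 0,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows))
    return(data.frame(cluster_id = character(0), mirna_a = character(0),
                      fce_a = numeric(0), padj_a = numeric(0),
                      mirna_b = character(0), fce_b = numeric(0),
                      padj_b = numeric(0), same_direction = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Repeated-impact subset across two comparisons
#'
#' Identifies miRNAs repeatedly affected in two comparisons sharing the
#' same reference group: candidates are the partner-confirmed miRNAs,
#' their partners, and any cluster-linked strands meeting the secondary
#' threshold in the first comparison; members are the candidates that also
#' meet the secondary threshold in the second comparison. The
#' cross-comparison R-squared of the candidates' FCE pairs quantifies the
#' agreement (all candidate rows by default, `members_only = TRUE`
#' restricts it to the final subset).
#'
#' @param de1,de2 Two [de_table()] results with a common `group_ref`.
#' @param confirmed A [confirm_by_partner()] result computed from `de1`.
#' @param reference The `mir_reference` (for cluster links).
#' @param alpha_secondary Secondary padj threshold (strict `<`).
#' @param members_only Restrict the R-squared to members.
#' @return An object of class `repeated_impact`: list with `members`
#'   (character), `dropped` (candidates failing in the second comparison),
#'   `table` (data.frame `mirna`, `fce1`, `padj1`, `fce2`, `padj2`,
#'   `member`) and `r_squared`.
#' @export
repeated_impact <- function(de1, de2, confirmed, reference,
                            alpha_secondary = 5e-2, members_only = FALSE) {
  stopifnot(inherits(de1, "de_result"), inherits(de2, "de_result"))
  if (!identical(attr(de1, "group_ref"), attr(de2, "group_ref")))
    stop_cfg("the two comparisons must share the reference group")
  mt <- mature_table(reference)

  cand <- unique(c(confirmed$mirna, confirmed$partner))
  hp <- mt$hairpin_id[match(cand, mt$mature)]
  cl <- unique(mt$cluster_id[mt$hairpin_id %in% hp])
  linked <- setdiff(mt$mature[mt$cluster_id %in% cl], cand)
  linked <- linked[linked %in% de1$mirna &
                     de1$padj[match(linked, de1$mirna)] < alpha_secondary]
  cand <- c(cand, linked)

  tab <- data.frame(
    mirna = cand,
    fce1 = de1$fce[match(cand, de1$mirna)],
    padj1 = de1$padj[match(cand, de1$mirna)],
    fce2 = de2$fce[match(cand, de2$mirna)],
    padj2 = de2$padj[match(cand, de2$mirna)],
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$member <- !is.na(tab$padj2) & tab$padj2 < alpha_secondary

  sub <- if (members_only) tab[tab$member, , drop = FALSE] else tab
  sub <- sub[complete.cases(sub[, c("fce1", "fce2")]), , drop = FALSE]
  r2 <- if (nrow(sub) >= 3L) r_squared(sub$fce1, sub$fce2) else NA_real_

  structure(list(members = tab$mirna[tab$member],
                 dropped = tab$mirna[!tab$member],
                 table = tab, r_squared = r2),
            class = "repeated_impact")
}

#' @export
print.repeated_impact <- function(x, ...) {
  cat("repeated_impact:", length(x$members), "member(s);",
      length(x$dropped), "candidate(s) dropped in the second comparison\n")
  if (!is.na(x$r_squared))
    cat("  cross-comparison FCE R^2 =", round(x$r_squared, 2), "\n")
  invisible(x)
}
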