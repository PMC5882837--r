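#' Bundled published summary tables
#'
#' Plain-text copies of the published rat arcuate-nucleus miRNome study
#' tables that the package's validation statistics are checked against:
#' the per-group variability summary (expressed miRNA counts, MAX/MIN
#' mean/SD, hypervariable counts), the two miRNA/partner-miRNA
#' differential-expression tables (HF-C vs C-C and HF-HF vs C-C), and the
#' repeated-impact candidate table with FCE/padj in both perinatal
#' comparisons. Values are as printed (FCEs to one decimal); they are
#' inputs for arithmetic validation, not outputs of this package.
#'
#' @param table One of `"variability_summary"`, `"de_pairs_HF-C"`,
#'   `"de_pairs_HF-HF"`, `"repeated_impact"`.
#' @return data.frame of the requested table.
#' @export
#' @examples
#' head(published_table("de_pairs_HF-C"))
published_table <- function(table = c("variability_summary",
                                      "de_pairs_HF-C", "de_pairs_HF-HF",
                                      "repeated_impact")) {
  table <- match.arg(table)
  file <- switch(table,
    "variability_summary" = "group_variability_summary.tsv",
    "de_pairs_HF-C" = "de_pairs_HF-C_vs_C-C.tsv",
    "de_pairs_HF-HF" = "de_pairs_HF-HF_vs_C-C.tsv",
    "repeated_impact" = "repeated_impact_fce.tsv"
  )
  path <- system.file("extdata", file, package = "mirnome",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
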