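# small fixture builders shared across test files

tiny_config <- function(seed = 1, ...) {
  sim_config(n_hairpins = 8, n_groups = 2, n_replicates = 3,
             group_labels = c("ctrl", "trt"), log_mean = log(30),
             log_sd = 0.5, p_single_arm = 0, seed = seed, ...)
}

# a hand-built two-hairpin reference with known sequences
manual_reference <- function() {
  hairpins <- data.frame(
    hairpin_id = c("hpA", "hpB"),
    cluster_id = c("clX", "clX"),
    name_5p = c("hpA-5p", "hpB-5p"),
    name_3p = c("hpA-3p", NA),
    seq_5p = c("ACGTACGTACGTACGTACGTAC", "TTGCATTGCATTGCATTGCATT"),
    seq_3p = c("GGCCAAGGCCAAGGCCAAGGCC", NA),
    stringsAsFactors = FALSE
  )
  structure(list(hairpins = hairpins,
                 clusters = list(clX = c("hpA", "hpB"))),
            class = "mir_reference")
}

# wrap a plain data.frame as a de_result for concordance unit tests
manual_de <- function(df, group_ref = "C-C", group_trt = "HF-C",
                      alpha_primary = 1e-2, alpha_secondary = 5e-2) {
  df$tier <- ifelse(df$padj < alpha_primary, 1L,
                    ifelse(df$padj < alpha_secondary, 2L, NA_integer_))
  structure(df, group_ref = group_ref, group_trt = group_trt,
            test = "nb", m = nrow(df), alpha_primary = alpha_primary,
            alpha_secondary = alpha_secondary,
            class = c("de_result", "data.frame"))
}

# two-group config with a ladder of planted arm-concordant effects,
# used for concordance and sensitivity checks
effect_ladder_config <- function(seed, fces, attenuation = 1,
                                 n_hairpins = 100) {
  base <- sim_config(n_hairpins = n_hairpins, n_groups = 2,
                     n_replicates = 6, group_labels = c("ctrl", "trt"),
                     p_single_arm = 0, seed = seed)
  hp <- make_reference(base)$hairpins
  eff <- data.frame(mature = hp$name_5p[10 + seq_along(fces)],
                    groups = "trt", fce = fces,
                    partner_attenuation = attenuation,
                    stringsAsFactors = FALSE)
  sim_config(n_hairpins = n_hairpins, n_groups = 2, n_replicates = 6,
             group_labels = c("ctrl", "trt"), p_single_arm = 0,
             planted_effects = eff, effect_min_baseline = 300,
             seed = seed)
}
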