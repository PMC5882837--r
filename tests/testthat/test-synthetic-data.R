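test_that("make_reference builds valid cluster partitions and strands", {
  cfg <- sim_config(n_hairpins = 3, p_single_arm = 0, seed = 1)
  ref <- make_reference(cfg)
  expect_equal(nrow(ref$hairpins), 3L)
  # no clusters declared: three singletons, six mature strands
  expect_length(ref$clusters, 3L)
  expect_true(all(lengths(ref$clusters) == 1L))
  mt <- mature_table(ref)
  expect_equal(nrow(mt), 6L)
  expect_false(anyDuplicated(mt$mature) > 0)
  expect_false(anyDuplicated(mt$sequence) > 0)
  expect_true(all(nchar(mt$sequence) >= 20 & nchar(mt$sequence) <= 24))
  # partner links are mutual
  expect_equal(mt$partner[match(mt$partner, mt$mature)], mt$mature)

  cfg3 <- sim_config(n_hairpins = 3, p_single_arm = 0,
                     clusters = list(all3 = 1:3), seed = 1)
  ref3 <- make_reference(cfg3)
  expect_length(ref3$clusters, 1L)
  expect_length(ref3$clusters$all3, 3L)
})

test_that("fixed seed makes every generator output reproducible", {
  cfg <- tiny_config(seed = 9, junk_fraction = 0.1)
  ref1 <- make_reference(cfg); ref2 <- make_reference(cfg)
  expect_identical(ref1, ref2)
  c1 <- simulate_counts(ref1, cfg); c2 <- simulate_counts(ref2, cfg)
  expect_identical(c1, c2)
  r1 <- simulate_reads(c1, ref1, cfg); r2 <- simulate_reads(c2, ref2, cfg)
  expect_identical(r1, r2)
})

test_that("configuration errors are caught", {
  expect_error(sim_config(n_hairpins = 0), "positive integer")
  expect_error(sim_config(n_hairpins = 5, clusters = list(a = c(1, 1))),
               "distinct")
  expect_error(sim_config(n_hairpins = 5,
                          hypervariable_log_sd = c(ghost = 1)),
               "not declared")
  eff <- data.frame(mature = "x", groups = "nowhere", fce = 2,
                    partner_attenuation = 1)
  expect_error(sim_config(n_hairpins = 5, planted_effects = eff),
               "unknown group")
  cfg <- tiny_config()
  ref <- make_reference(cfg)
  bad <- data.frame(mature = "not-a-strand", groups = "trt", fce = 2,
                    partner_attenuation = 1)
  cfg_bad <- tiny_config(planted_effects = bad)
  expect_error(simulate_counts(ref, cfg_bad), "unknown mature")
})

test_that("dispersion zero gives the deterministic noise-free limit", {
  cfg <- tiny_config(dispersion = 0)
  ref <- make_reference(cfg)
  x <- simulate_counts(ref, cfg)
  # every replicate column equals the rounded per-strand baseline
  expect_true(all(x$counts == x$counts[, 1]))
  expect_true(all(x$counts == round(x$counts)))
})

test_that("planted fold-change converges to its target over many replicates", {
  base <- sim_config(n_hairpins = 4, n_groups = 2, n_replicates = 500,
                     group_labels = c("ctrl", "trt"), p_single_arm = 0,
                     log_sd = 0.5, seed = 4)
  hp <- make_reference(base)$hairpins
  eff <- data.frame(mature = hp$name_5p[1], groups = "trt", fce = 0.5,
                    partner_attenuation = 0.5)
  cfg <- sim_config(n_hairpins = 4, n_groups = 2, n_replicates = 500,
                    group_labels = c("ctrl", "trt"), p_single_arm = 0,
                    log_sd = 0.5, planted_effects = eff, seed = 4)
  ref <- make_reference(cfg)
  x <- simulate_counts(ref, cfg)
  trt <- x$groups == "trt"
  ratio <- rowMeans(x$counts[, trt]) / rowMeans(x$counts[, !trt])
  expect_equal(unname(ratio[hp$name_5p[1]]), 0.5, tolerance = 0.05)
  # attenuated partner: fce^0.5
  expect_equal(unname(ratio[hp$name_3p[1]]), sqrt(0.5), tolerance = 0.05)
  # untouched strands stay at 1
  expect_equal(unname(ratio[hp$name_5p[2]]), 1, tolerance = 0.05)
})

test_that("simulated counts match the NB mean-variance law", {
  cfg <- sim_config(n_hairpins = 3, n_groups = 1, n_replicates = 10000,
                    p_single_arm = 0, log_sd = 0.3, dispersion = 0.1,
                    dispersion_log_sd = 0, seed = 11)
  ref <- make_reference(cfg)
  x <- simulate_counts(ref, cfg)
  mu_hat <- rowMeans(x$counts)
  v_hat <- apply(x$counts, 1, var)
  expect_equal(v_hat, mu_hat + 0.1 * mu_hat^2, tolerance = 0.1)
})

test_that("a shared cluster factor makes member expression co-vary", {
  # under a common dispersion the shared lognormal factor (log-sd 1)
  # dominates count noise; per-strand dispersion tails lower the mean
  # score to ~0.87 and are exercised elsewhere
  scores <- vapply(1:10, function(s) {
    cfg <- sim_config(n_hairpins = 20, n_groups = 1, n_replicates = 6,
                      p_single_arm = 0, dispersion_log_sd = 0,
                      clusters = list(hv = 1:3),
                      hypervariable_log_sd = c(hv = 1), seed = s)
    ref <- make_reference(cfg)
    x <- normalize_counts(simulate_counts(ref, cfg))
    members <- mature_table(ref)
    members <- members$mature[members$cluster_id == "hv"]
    covariation_score(x, members, "G1")$score
  }, numeric(1))
  expect_gt(mean(scores), 0.9)
})

test_that("simulated reads realize count cells exactly and junk is short", {
  cfg <- tiny_config(seed = 3)
  ref <- make_reference(cfg)
  x <- simulate_counts(ref, cfg)
  batch <- simulate_reads(x, ref, cfg)
  barcodes <- attr(batch, "barcodes")
  mt <- mature_table(ref)
  # count cell k for a strand -> exactly k reads in that library whose
  # insert equals the strand's sequence
  lib <- colnames(x$counts)[2]
  strand <- mt$mature[5]
  in_lib <- grepl(paste0("^", lib, "_"), batch$read_id)
  expected_read <- paste0(mt$sequence[5], barcodes[[lib]], cfg$adapter3)
  expect_equal(sum(batch$sequence[in_lib] == expected_read),
               unname(x$counts[strand, lib]))
  # junk_fraction = 0: every insert length is a mature length (20-24)
  ins <- nchar(batch$sequence) - 11L - nchar(cfg$adapter3)
  expect_true(all(ins >= 20 & ins <= 24))

  cfgj <- tiny_config(seed = 3, junk_fraction = 0.2)
  bj <- simulate_reads(simulate_counts(ref, cfgj), ref, cfgj)
  insj <- nchar(bj$sequence) - 11L - nchar(cfgj$adapter3)
  expect_true(any(insj < 15))
  expect_true(all(insj[insj < 20] < 15))  # junk is always sub-filter length

  expect_error(check_barcodes(c("AAAAAAAAAAA", "AAAAAAAAAAA")), "collision")
})

test_that("FASTQ and reference round-trip through their file formats", {
  cfg <- tiny_config(seed = 5)
  ref <- make_reference(cfg)
  x <- simulate_counts(ref, cfg)
  batch <- simulate_reads(x, ref, cfg)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(batch, fq)
  back <- read_fastq(fq)
  expect_equal(back$read_id, batch$read_id)
  expect_equal(back$sequence, batch$sequence)
  expect_equal(back$quality, batch$quality)

  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_reference(ref, fa, tsv)
  ref_back <- read_reference(fa, tsv)
  expect_equal(ref_back$hairpins, ref$hairpins)
  expect_equal(mature_table(ref_back), mature_table(ref))
})
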