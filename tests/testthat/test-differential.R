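test_that("exact Mann-Whitney matches enumeration oracles", {
  expect_equal(mw_exact_test(c(3, 1, 4, 1, 5, 9), c(3, 1, 4, 1, 5, 9)), 1)
  expect_equal(mw_exact_test(1:6, 7:12), 2 / 924)
  expect_equal(mw_exact_test(7:12, 1:6), 2 / 924)
  expect_equal(mw_exact_test(c(1, 2), c(3, 4)), 1 / 3)
  expect_error(mw_exact_test(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney is symmetric and matches wilcox.test", {
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6) + i / 10
    p <- mw_exact_test(a, b)
    expect_equal(p, mw_exact_test(b, a))
    expect_gte(p, 2 / 924)
    # independent reference implementation (exact path, no ties)
    expect_equal(p, wilcox.test(a, b, exact = TRUE)$p.value)
  }
  # mid-ranks: tied data still yields a valid exact p
  expect_equal(mw_exact_test(c(1, 1, 2), c(1, 2, 2)), 1)
})

test_that("NB exact test reduces to Poisson-conditional enumeration", {
  # symmetric case: all splits at most as likely as the observed one
  expect_equal(nb_exact_test(c(5, 5, 5), c(5, 5, 5), rep(1, 3), rep(1, 3),
                             0.05), 1)
  expect_equal(nb_exact_test(integer(3), integer(3), rep(1, 3), rep(1, 3),
                             0.05), 1)

  # brute-force oracle at alpha -> 0: condition Poisson totals on the sum
  brute_poisson <- function(ka, kb, sa, sb) {
    tot <- ka + kb
    probs <- vapply(0:tot, function(k)
      dpois(k, sa) * dpois(tot - k, sb), numeric(1))
    probs <- probs / sum(probs)
    sum(probs[probs <= probs[ka + 1] * (1 + 1e-7)])
  }
  # worked case: totals 10 vs 0, equal effective sizes, 11 splits
  expect_equal(nb_exact_test(c(4, 3, 3), c(0, 0, 0), rep(1, 3), rep(1, 3), 0),
               brute_poisson(10, 0, 3, 3), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    a <- rpois(4, 20); b <- rpois(5, 15)   # totals well below 200
    sa <- runif(4, 0.5, 2); sb <- runif(5, 0.5, 2)
    q <- (sum(a) + sum(b)) / (sum(sa) + sum(sb))
    expect_equal(nb_exact_test(a, b, sa, sb, 0),
                 brute_poisson(sum(a), sum(b), q * sum(sa), q * sum(sb)),
                 tolerance = 1e-10)
  }
  expect_error(nb_exact_test(c(1.5, 2), c(1, 1), c(1, 1), c(1, 1), 0.1),
               "integers")
})

test_that("dispersion estimation recovers a known common dispersion", {
  cfg <- sim_config(n_hairpins = 150, n_groups = 2, n_replicates = 6,
                    group_labels = c("a", "b"), p_single_arm = 0,
                    dispersion = 0.1, dispersion_log_sd = 0, seed = 3)
  x <- normalize_counts(simulate_counts(make_reference(cfg), cfg))
  d <- estimate_dispersions(x)
  expect_equal(attr(d, "df"), 10L)
  expect_equal(median(d$raw), 0.1, tolerance = 0.25)
  expect_true(all(d$final >= d$trend - 1e-12))
  expect_true(all(d$final >= 1e-8))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.03, 0.04)),
               c(0.004, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # independent literal step-up oracle + order invariance
  step_up <- function(p) {
    m <- length(p); o <- order(p)
    adj <- m * p[o] / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(2)
  p <- runif(37)
  expect_equal(bh_adjust(p), step_up(p))
  perm <- sample(length(p))
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_true(all(bh_adjust(p) >= p))
})

test_that("FCE is the ratio of group means of normalized expression", {
  m <- rbind(c(10, 10, 10, 20, 20, 20),
             c(30, 30, 30, 30, 30, 30),
             rep(500, 6))
  dimnames(m) <- list(c("up2", "flat", "anchor"), paste0("l", 1:6))
  x <- normalize_counts(mir_counts(m, rep(c("ref", "trt"), each = 3)))
  expect_equal(fce(x, "up2", "ref", "trt"), 2)
  expect_equal(fce(x, "flat", "ref", "trt"), 1)
  z <- m; z["up2", 1:3] <- 0L
  xz <- normalize_counts(mir_counts(z, rep(c("ref", "trt"), each = 3)))
  expect_warning(res <- fce(xz, "up2", "ref", "trt"), "zero reference")
  expect_true(is.na(res))

  # planted effect recovered within sampling error
  cfg <- effect_ladder_config(31, fces = 0.5)
  ref <- make_reference(cfg)
  xs <- normalize_counts(simulate_counts(ref, cfg))
  expect_equal(fce(xs, cfg$planted_effects$mature[1], "ctrl", "trt"),
               0.5, tolerance = 0.2)
})

test_that("de_table assembles FCE, p, padj and tiers over the tested set", {
  cfg <- effect_ladder_config(17, fces = c(0.4, 3))
  ref <- make_reference(cfg)
  x <- normalize_counts(simulate_counts(ref, cfg))
  de <- de_table(x, "ctrl", "trt")
  expect_s3_class(de, "de_result")
  expect_equal(attr(de, "m"), nrow(de))
  expect_equal(de$padj, bh_adjust(de$pvalue))
  planted <- cfg$planted_effects$mature
  expect_true(all(de$tier[match(planted, de$mirna)] == 1L))
  vol <- volcano_data(de)
  expect_equal(vol$log2_fce, log2(de$fce))
  expect_error(de_table(x, "ctrl", "ctrl"), "must differ")

  # single-miRNA matrix: padj equals p
  m1 <- matrix(c(40L, 42L, 38L, 90L, 85L, 95L), 1,
               dimnames = list("only", paste0("l", 1:6)))
  x1 <- normalize_counts(mir_counts(m1, rep(c("a", "b"), each = 3)))
  d1 <- de_table(x1, "a", "b", test = "mw")
  expect_equal(d1$padj, d1$pvalue)
})

test_that("most planted effects across the published FCE range reach tier 2", {
  fces <- rep(c(0.4, 0.5, 0.6, 1.4, 1.7, 2.0), 3)
  cfg <- effect_ladder_config(23, fces = fces, n_hairpins = 150)
  ref <- make_reference(cfg)
  x <- normalize_counts(simulate_counts(ref, cfg))
  de <- de_table(x, "ctrl", "trt")
  tiers <- de$tier[match(cfg$planted_effects$mature, de$mirna)]
  expect_gt(mean(!is.na(tiers)), 0.5)
})

test_that("a null simulation yields no tier-1 calls", {
  for (s in 1:3) {
    cfg <- sim_config(n_hairpins = 150, n_groups = 2, n_replicates = 6,
                      group_labels = c("a", "b"), p_single_arm = 0,
                      seed = s)
    x <- normalize_counts(simulate_counts(make_reference(cfg), cfg))
    de <- de_table(x, "a", "b")
    expect_equal(sum(de$tier == 1L, na.rm = TRUE), 0L)
  }
})

test_that("the Mann-Whitney route is available end to end", {
  cfg <- effect_ladder_config(41, fces = c(0.4, 3))
  ref <- make_reference(cfg)
  x <- normalize_counts(simulate_counts(ref, cfg))
  de <- de_table(x, "ctrl", "trt", test = "mw")
  expect_true(all(de$pvalue >= 2 / 924))
  planted <- cfg$planted_effects$mature
  expect_true(all(de$pvalue[match(planted, de$mirna)] == 2 / 924))
})
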