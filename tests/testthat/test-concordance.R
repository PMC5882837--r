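test_that("r_squared matches hand computations and invariances", {
  x <- c(1, 2, 3)
  expect_equal(r_squared(x, 2 * x + 1), 1)
  expect_equal(r_squared(c(1, 2, 3), c(1, 3, 2)), 0.25)
  set.seed(4)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(r_squared(a, b), r_squared(b, a))
  expect_equal(r_squared(3 * a - 2, b), r_squared(a, b))
  expect_warning(res <- r_squared(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(res))
  expect_error(r_squared(1:2, 1:2), ">= 3")
})

test_that("pair_partners pairs tier-1 strands with expressed partners", {
  ref <- manual_reference()
  de <- manual_de(data.frame(
    mirna = c("hpA-5p", "hpA-3p", "hpB-5p"),
    fce = c(0.5, 0.6, 3.0),
    padj = c(0.005, 0.03, 0.002),
    stringsAsFactors = FALSE))
  pp <- pair_partners(de, ref)
  # hpA-5p is tier-1 with expressed partner; hpB-5p has no second arm
  expect_equal(pp$pairs$mirna, "hpA-5p")
  expect_equal(pp$pairs$partner, "hpA-3p")
  expect_equal(pp$pairs$partner_padj, 0.03)
  expect_equal(pp$pairs$hairpin_id, "hpA")
  expect_equal(pp$partnerless, "hpB-5p")

  # partner tested but hairpin emits one strand only -> never paired
  de2 <- manual_de(data.frame(mirna = "hpB-5p", fce = 2, padj = 0.001,
                              stringsAsFactors = FALSE))
  pp2 <- pair_partners(de2, ref)
  expect_equal(nrow(pp2$pairs), 0L)
  expect_equal(pp2$partnerless, "hpB-5p")

  de3 <- manual_de(data.frame(mirna = "ghost-5p", fce = 2, padj = 0.001,
                              stringsAsFactors = FALSE))
  expect_error(pair_partners(de3, ref), "absent from the reference")
})

test_that("partner confirmation uses a strict secondary threshold", {
  ref <- manual_reference()
  de <- manual_de(data.frame(
    mirna = c("hpA-5p", "hpA-3p"),
    fce = c(0.5, 0.6),
    padj = c(0.005, 0.05),   # partner exactly at the threshold
    stringsAsFactors = FALSE))
  pp <- pair_partners(de, ref)
  expect_equal(nrow(confirm_by_partner(pp)), 0L)   # 0.05 is not < 0.05
  de$padj[2] <- 0.049
  pp2 <- pair_partners(manual_de(as.data.frame(de)), ref)
  expect_equal(confirm_by_partner(pp2)$mirna, "hpA-5p")
  de$padj[2] <- 1
  pp3 <- pair_partners(manual_de(as.data.frame(de)), ref)
  expect_equal(nrow(confirm_by_partner(pp3)), 0L)
})

test_that("cotranscription check reports same-cluster pairs with direction", {
  ref <- manual_reference()  # hpA and hpB share cluster clX
  de <- manual_de(data.frame(
    mirna = c("hpA-5p", "hpA-3p", "hpB-5p"),
    fce = c(4.8, 3.4, 3.3),
    padj = c(0.009, 0.031, 0.050),
    stringsAsFactors = FALSE))
  rep <- cotranscription_check(de, ref)
  # only pairs containing the tier-1 member (hpA-5p) are reported; the
  # (hpA-3p, hpB-5p) pair has no tier-1 member and is skipped
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$same_direction)) # all FCEs above 1
  key <- paste(rep$mirna_a, rep$mirna_b)
  expect_true("hpA-5p hpB-5p" %in% key)

  # opposite directions are flagged
  de2 <- manual_de(data.frame(
    mirna = c("hpA-5p", "hpB-5p"), fce = c(2, 0.5),
    padj = c(0.001, 0.02), stringsAsFactors = FALSE))
  rep2 <- cotranscription_check(de2, ref)
  expect_false(any(rep2$same_direction))

  # singleton miRNA in its own cluster: no report rows
  solo <- manual_reference()
  solo$hairpins$cluster_id <- c("c1", "c2")
  solo$hairpins$name_3p[1] <- NA; solo$hairpins$seq_3p[1] <- NA
  de3 <- manual_de(data.frame(mirna = "hpA-5p", fce = 2, padj = 0.001,
                              stringsAsFactors = FALSE))
  expect_equal(nrow(cotranscription_check(de3, solo)), 0L)
})

test_that("repeated impact intersects confirmed calls across comparisons", {
  ref <- manual_reference()
  de1 <- manual_de(data.frame(
    mirna = c("hpA-5p", "hpA-3p", "hpB-5p"),
    fce = c(0.5, 0.6, 3.3),
    padj = c(0.005, 0.02, 0.04),
    stringsAsFactors = FALSE), group_trt = "HF-C")
  de2 <- manual_de(data.frame(
    mirna = c("hpA-5p", "hpA-3p", "hpB-5p"),
    fce = c(0.4, 0.5, 3.6),
    padj = c(0.005, 0.42, 0.03),
    stringsAsFactors = FALSE), group_trt = "HF-HF")
  confirmed <- confirm_by_partner(pair_partners(de1, ref))
  ri <- repeated_impact(de1, de2, confirmed, ref)
  # hpA-3p fails the second comparison and is dropped with a note;
  # hpB-5p joins through the cluster link and survives
  expect_setequal(ri$members, c("hpA-5p", "hpB-5p"))
  expect_equal(ri$dropped, "hpA-3p")
  expect_equal(nrow(ri$table), 3L)
  expect_true(all(ri$members %in% ri$table$mirna))

  # cross-comparison R2 over all candidate rows vs members only
  expect_equal(ri$r_squared, r_squared(ri$table$fce1, ri$table$fce2))
  rim <- repeated_impact(de1, de2, confirmed, ref, members_only = TRUE)
  expect_true(is.na(rim$r_squared) || rim$r_squared >= 0)  # < 3 members

  # no significant calls in the second comparison -> empty set
  de2n <- de2; de2n$padj <- rep(0.9, 3)
  ri0 <- repeated_impact(de1, manual_de(as.data.frame(de2n),
                                        group_trt = "HF-HF"),
                         confirmed, ref)
  expect_length(ri0$members, 0L)

  # mismatched reference group is an error
  de2b <- manual_de(as.data.frame(de2), group_ref = "other")
  expect_error(repeated_impact(de1, de2b, confirmed, ref),
               "share the reference")
})

test_that("arm concordance of pair-level FCEs tracks partner attenuation", {
  fces <- exp(seq(log(0.4), log(3), length.out = 12))
  one <- function(seed, att) {
    cfg <- effect_ladder_config(seed, fces = fces, attenuation = att)
    ref <- make_reference(cfg)
    x <- normalize_counts(simulate_counts(ref, cfg))
    pp <- pair_partners(de_table(x, "ctrl", "trt"), ref)
    if (nrow(pp$pairs) < 3) return(NA_real_)
    r_squared(pp$pairs$fce, pp$pairs$partner_fce)
  }
  r_full <- one(1, att = 1)
  r_none <- one(1, att = 0)
  expect_gt(r_full, 0.6)
  expect_lt(r_none, r_full)
})
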