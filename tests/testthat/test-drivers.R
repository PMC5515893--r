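# helper: fc_table straight from component values
fc_from_components <- function(rna, eff, ids = sprintf("g%03d", seq_along(rna))) {
  out <- data.frame(gene_id = ids, log2_rna_fc = rna,
                    log2_rpf_fc = rna + eff, log2_eff_fc = eff,
                    stringsAsFactors = FALSE)
  class(out) <- c("fc_table", "data.frame")
  out
}

test_that("fold changes follow the closed form and the additive identity", {
  m <- cbind(
    RPF_A = c(10, 5), RPF_B = c(40, 5),
    RNA_A = c(10, 5), RNA_B = c(10, 5)
  )
  rownames(m) <- c("g1", "g2")
  es <- make_es(m, assay = c("RPF", "RPF", "RNA", "RNA"),
                condition = c("A", "B", "A", "B"), replicate = 1,
                unit = "RPKM")
  fc0 <- fold_changes(es, "A", "B", pseudocount = 0)
  expect_equal(fc0$log2_rpf_fc, c(2, 0))       # 10 -> 40 with pseudocount 0
  expect_equal(fc0$log2_rna_fc, c(0, 0))
  expect_identical(fc0$log2_eff_fc, fc0$log2_rpf_fc - fc0$log2_rna_fc)
  # identical conditions -> all zero
  fcAA <- fold_changes(es, "A", "A")
  expect_equal(fcAA$log2_rpf_fc, c(0, 0))
  expect_equal(fcAA$log2_eff_fc, c(0, 0))
  expect_error(fold_changes(es, "A", "C"), "pairing")
})

test_that("fold changes recover simulated effects", {
  # a small, balanced regulated fraction keeps library composition stable
  # so RPKM fold changes estimate the true per-gene effects without a
  # normalisation shift
  cfg <- sim_config(n_genes = 2000, nb_dispersion = 0.01,
                    n_families = 0, targets_per_family = 0,
                    class_fractions = list(brown = c(synergistic_up = 0.02,
                                                     synergistic_down = 0.02)),
                    effect_syn_range = c(1.0, 1.5), seed = 31)
  exp <- simulate_experiment(cfg)
  kept <- filter_detected(exp$counts)
  rp <- rpkm(subset_expr(exp$counts, genes = kept), exp$ann$genes)
  fc <- fold_changes(rp, "BATD0", "BATD5")
  truth <- exp$truth$effects$brown
  m <- match(fc$gene_id, truth$gene_id)
  reg <- truth$class[m] != "unregulated"
  err_rna <- fc$log2_rna_fc[reg] - truth$log2_rna_fc[m][reg]
  err_eff <- fc$log2_eff_fc[reg] - truth$log2_eff_fc[m][reg]
  # typical per-gene error within +-0.2 log2 and no systematic shift
  expect_lt(stats::median(abs(err_rna)), 0.2)
  expect_lt(stats::median(abs(err_eff)), 0.2)
  expect_lt(abs(mean(err_rna)), 0.1)
  expect_lt(abs(mean(err_eff)), 0.1)
})

test_that("the classification rule assigns the documented groups", {
  fc <- fc_from_components(
    rna = c(0.3, -1.8, 2.5, 0.1, 1.6, -3.8, 1.4, -1.4),
    eff = c(2.0, -0.4, 2.2, -2.4, -3.8, 1.6, 1.4, 1.4)
  )
  asg <- classify_drivers(fc, rpf_fold_threshold = 4)
  got <- stats::setNames(asg$group, asg$gene_id)
  expect_equal(unname(got["g001"]), 1L)   # translation-driven up
  expect_equal(unname(got["g002"]), 6L)   # rna-driven down
  expect_equal(unname(got["g003"]), 2L)   # synergistic up
  expect_equal(unname(got["g004"]), 4L)   # translation-driven down
  # opposite signs, |eff| > |rna|: translation wins; direction from RPF sign
  expect_equal(unname(got["g005"]), 4L)
  # opposite signs, |rna| > |eff|: rna wins
  expect_equal(unname(got["g006"]), 6L)
  # same-sign components of equal size -> synergistic up
  expect_equal(unname(got["g007"]), 2L)
  expect_false("g008" %in% names(got))    # rpf = 0, below threshold
})

test_that("the larger-magnitude component wins on opposite signs", {
  fc <- fc_from_components(rna = c(3.1), eff = c(-1.1))
  asg <- classify_drivers(fc, rpf_fold_threshold = 4)
  expect_equal(asg$category, "rna_driven")
  fc2 <- fc_from_components(rna = c(-1.5), eff = c(3.5))
  asg2 <- classify_drivers(fc2, rpf_fold_threshold = 4)
  expect_equal(asg2$category, "translation_driven")
  expect_equal(asg2$group, 1L)
})

test_that("classification partition is exhaustive and exclusive", {
  withr::with_seed(99, {
    for (i in 1:20) {
      fc <- fc_from_components(rna = stats::rnorm(300, 0, 2),
                               eff = stats::rnorm(300, 0, 2))
      for (thr in c(2, 4)) {
        asg <- classify_drivers(fc, rpf_fold_threshold = thr)
        passing <- fc$gene_id[abs(fc$log2_rpf_fc) >= log2(thr)]
        expect_setequal(asg$gene_id, passing)
        expect_equal(anyDuplicated(asg$gene_id), 0L)
        expect_true(all(asg$group %in% 1:6))
        # group <-> category <-> direction coherence
        expect_true(all((asg$group %in% c(1, 4)) ==
                          (asg$category == "translation_driven")))
        expect_true(all((asg$group %in% c(2, 5)) ==
                          (asg$category == "synergistic")))
        expect_true(all((asg$group <= 3) == (asg$direction == "up")))
      }
    }
  })
})

test_that("driver summaries reproduce the published worked examples", {
  # brown adipogenesis: groups (4, 54, 331, 107, 203, 260), total 959
  s1 <- summarize_driver_classes(c(4, 54, 331, 107, 203, 260))
  expect_equal(s1$total, 959)
  expect_equal(unname(s1$counts["translation_driven"]), 111)
  expect_equal(unname(s1$counts["synergistic"]), 257)
  expect_equal(unname(s1$percent["translation_driven"]), 11.6)
  expect_equal(unname(s1$percent["synergistic"]), 26.8)
  # white adipogenesis: groups (0, 7, 230, 14, 61, 201), total 513
  s2 <- summarize_driver_classes(c(0, 7, 230, 14, 61, 201))
  expect_equal(s2$total, 513)
  expect_equal(unname(s2$counts["translation_driven"]), 14)
  expect_equal(unname(s2$percent["translation_driven"]), 2.7)
  expect_equal(unname(s2$counts["synergistic"]), 68)
  expect_equal(unname(s2$percent["synergistic"]), 13.3)
  # BAT vs WAT: groups (19, 88, 288, 10, 277, 574), total 1256
  s3 <- summarize_driver_classes(c(19, 88, 288, 10, 277, 574))
  expect_equal(s3$total, 1256)
  expect_equal(unname(s3$percent["translation_driven"]), 2.3)
  expect_equal(unname(s3$percent["synergistic"]), 29.1)
  # percentages sum to 100 within rounding
  for (s in list(s1, s2, s3)) expect_lt(abs(sum(s$percent) - 100), 0.15)
  # all-zero counts -> empty flag
  expect_true(summarize_driver_classes(rep(0, 6))$empty)
})

test_that("contribution estimator hits the degenerate extremes", {
  withr::with_seed(7, {
    n <- 400
    rna <- stats::rnorm(n, 0, 2)
    noise <- function() stats::rnorm(n, 0, 0.05)
    # all regulation RNA-driven: eff ~ 0
    rep1 <- fc_from_components(rna + noise(), noise())
    rep2 <- fc_from_components(rna + noise(), noise())
    est <- contribution_ratio(rep1, rep2)
    expect_true(est$reliable)
    expect_lt(est$eff_contribution_pct, 10)
    # all regulation Eff-driven
    eff <- stats::rnorm(n, 0, 2)
    rep1e <- fc_from_components(noise(), eff + noise())
    rep2e <- fc_from_components(noise(), eff + noise())
    este <- contribution_ratio(rep1e, rep2e)
    expect_gt(este$eff_contribution_pct, 90)
    # pure noise: r_rep ~ 0 -> unreliable flag
    repn1 <- fc_from_components(noise(), noise())
    repn2 <- fc_from_components(noise(), noise())
    estn <- suppressWarnings(contribution_ratio(repn1, repn2))
    if (!estn$reliable) expect_true(is.na(estn$eff_contribution_pct))
  })
})

test_that("delta-Eff ranking orders by the contrast difference", {
  fc1 <- fc_from_components(rna = c(0, 0, 0), eff = c(2, -1, 0),
                            ids = c("g1", "g2", "g3"))
  fc2 <- fc_from_components(rna = c(0, 0, 0), eff = c(0, 0, 0),
                            ids = c("g1", "g2", "g3"))
  r <- delta_eff_ranking(fc1, fc2)
  expect_identical(r$gene_id, c("g1", "g3", "g2"))
  expect_equal(r$delta_eff, c(2, 0, -1))
  # identical contrasts: all keys zero, gene-id order
  r0 <- delta_eff_ranking(fc1, fc1)
  expect_identical(r0$gene_id, c("g1", "g2", "g3"))
  expect_equal(r0$delta_eff, c(0, 0, 0))
  # permutation invariant of the analysed set
  expect_setequal(r$gene_id, fc1$gene_id)
})

test_that("genes with contrast-specific Eff up-regulation rank high", {
  withr::with_seed(123, {
    n <- 500
    ids <- sprintf("g%03d", 1:n)
    special <- ids[1:40]
    eff1 <- stats::rnorm(n, 0, 0.5)
    eff1[1:40] <- eff1[1:40] + 1.5            # extra Eff in contrast 1 only
    fc1 <- fc_from_components(stats::rnorm(n, 0, 0.5), eff1, ids)
    fc2 <- fc_from_components(stats::rnorm(n, 0, 0.5),
                              stats::rnorm(n, 0, 0.5), ids)
    r <- delta_eff_ranking(fc1, fc2)
    rank_special <- which(r$gene_id %in% special)
    wt <- stats::wilcox.test(rank_special,
                             which(!(r$gene_id %in% special)),
                             alternative = "less")
    expect_lt(wt$p.value, 0.01)
  })
})

test_that("median normalization removes a global composition shift", {
  # five genes, one truly regulated; RPKM renormalization shifts everything
  m <- cbind(
    RPF_A = c(10, 10, 10, 10, 10), RPF_B = c(80, 10, 10, 10, 10),
    RNA_A = c(10, 10, 10, 10, 10), RNA_B = c(10, 10, 10, 10, 10)
  )
  rownames(m) <- paste0("g", 1:5)
  es <- make_es(m, assay = c("RPF", "RPF", "RNA", "RNA"),
                condition = c("A", "B", "A", "B"), replicate = 1,
                unit = "RPKM")
  raw <- fold_changes(es, "A", "B", pseudocount = 0)
  cen <- fold_changes(es, "A", "B", pseudocount = 0, normalize = "median")
  # raw: g1 carries log2 8 = 3; unregulated genes 0 (RPKM given directly)
  expect_equal(raw$log2_rpf_fc, c(3, 0, 0, 0, 0))
  # centring subtracts the per-assay median (0 here): unchanged
  expect_equal(cen$log2_rpf_fc, raw$log2_rpf_fc)
  # add a global shift to every RPF fold change: centring removes it
  es2 <- es
  es2$mat[, "RPF_B_rep1"] <- es$mat[, "RPF_B_rep1"] * 2
  raw2 <- fold_changes(es2, "A", "B", pseudocount = 0)
  cen2 <- fold_changes(es2, "A", "B", pseudocount = 0, normalize = "median")
  expect_equal(raw2$log2_rpf_fc, c(4, 1, 1, 1, 1))
  expect_equal(cen2$log2_rpf_fc, c(3, 0, 0, 0, 0))
  # identity preserved under centring
  expect_identical(cen2$log2_eff_fc, cen2$log2_rpf_fc - cen2$log2_rna_fc)
  expect_equal(attr(cen2, "normalize"), "median")
})
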