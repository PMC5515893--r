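# helper: named expression values with family repression applied
repress <- function(values, targets, log2_strength) {
  values[names(values) %in% targets] <-
    values[names(values) %in% targets] * 2^(-log2_strength)
  values
}

test_that("family collapsing takes target unions and max site counts", {
  tab <- data.frame(
    mirna_id = c("miR-1a", "miR-1a", "miR-1b", "miR-1b", "miR-9"),
    gene_id = c("a", "b", "b", "c", "x"),
    n_sites = c(1, 2, 3, 1, 4),
    stringsAsFactors = FALSE
  )
  map <- data.frame(mirna_id = c("miR-1a", "miR-1b"),
                    family_id = c("miR-1", "miR-1"),
                    stringsAsFactors = FALSE)
  fams <- collapse_families(tab, map)
  m1 <- fams[fams$family_id == "miR-1", ]
  expect_setequal(m1$gene_id, c("a", "b", "c"))      # union of member targets
  expect_equal(m1$n_sites[m1$gene_id == "b"], 3)     # max over members
  # unmapped member becomes a singleton family
  expect_true("miR-9" %in% fams$family_id)
  # single-member family is the identity
  solo <- collapse_families(tab[5, , drop = FALSE])
  expect_equal(solo$gene_id, "x")
  expect_equal(solo$n_sites, 4)
  expect_error(collapse_families(tab[0, ]), "empty")
})

test_that("generator family count round-trips through collapsing", {
  cfg <- sim_config(n_genes = 400, n_families = 23, targets_per_family = 30,
                    seed = 14)
  ann <- generate_annotation(cfg)
  fams <- collapse_families(ann$targets)
  expect_equal(length(unique(fams$family_id)), 23)
})

test_that("within-tissue repression is detected on the right metric", {
  withr::with_seed(42, {
    n <- 3000
    ids <- sprintf("g%04d", 1:n)
    rna <- stats::setNames(rlnorm(n, log(30), 1), ids)
    eff <- stats::setNames(rlnorm(n, 0, 0.4), ids)
    targets <- sample(ids, 100)
    # -1 log2 repression applied to RNA only
    rna_rep <- repress(rna, targets, 1)
    rpf_rep <- rna_rep * eff                    # RPF inherits the RNA change
    rec_rna <- target_repression_within_tissue(rna_rep, targets,
                                               family_id = "f", metric = "RNA",
                                               tissue = "BAT")
    expect_false(rec_rna$skipped)
    expect_lt(rec_rna$ks_p, 1e-3)
    expect_lt(abs(rec_rna$ratio - 0.5), 0.15)   # ~0.5 on the linear scale
    expect_true(rec_rna$repressed)
    rec_rpf <- target_repression_within_tissue(rpf_rep, targets,
                                               metric = "RPF")
    expect_lt(rec_rpf$ks_p, 1e-3)
    # Eff untouched: null record
    rec_eff <- target_repression_within_tissue(eff, targets, metric = "Eff")
    expect_gt(rec_eff$ks_p, 0.05)
    expect_lt(abs(rec_eff$ratio - 1), 0.2)
  })
})

test_that("null targets give a calibrated null record", {
  withr::with_seed(6, {
    n <- 2000
    ids <- sprintf("g%04d", 1:n)
    vals <- stats::setNames(rlnorm(n, 3, 1), ids)
    ps <- vapply(1:100, function(i) {
      targets <- sample(ids, 50)
      target_repression_within_tissue(vals, targets)$ks_p
    }, 0)
    frac <- mean(ps < 0.05)
    expect_gt(frac, 0.0)
    expect_lt(frac, 0.12)
  })
})

test_that("families below min_targets are skipped with a flag", {
  vals <- withr::with_seed(16, stats::setNames(rlnorm(100), sprintf("g%03d", 1:100)))
  rec <- target_repression_within_tissue(vals, c("g001", "g002"),
                                         min_targets = 10)
  expect_true(rec$skipped)
  expect_true(is.na(rec$ratio))
})

test_that("cross-tissue shifts localise to the differentially used component", {
  withr::with_seed(13, {
    n <- 3000
    ids <- sprintf("g%04d", 1:n)
    targets <- sample(ids, 120)
    # targets repressed 1 log2 more strongly in BAT at the Eff level
    rna_fc <- rnorm(n, 0, 0.4)
    eff_fc <- rnorm(n, 0, 0.4)
    eff_fc[ids %in% targets] <- eff_fc[ids %in% targets] - 1
    fc <- data.frame(gene_id = ids, log2_rna_fc = rna_fc,
                     log2_rpf_fc = rna_fc + eff_fc, log2_eff_fc = eff_fc,
                     stringsAsFactors = FALSE)
    class(fc) <- c("fc_table", "data.frame")
    attr(fc, "contrast") <- "BAT_vs_WAT"
    rec_eff <- cross_tissue_target_shift(fc, targets, metric = "Eff",
                                         family_id = "f")
    expect_lt(rec_eff$ks_p, 0.01)
    expect_equal(rec_eff$direction, "left")
    expect_lt(rec_eff$ratio, 1)
    # RPF inherits the shift, RNA stays null
    rec_rpf <- cross_tissue_target_shift(fc, targets, metric = "RPF")
    expect_lt(rec_rpf$ks_p, 0.01)
    rec_rna <- cross_tissue_target_shift(fc, targets, metric = "RNA")
    expect_gt(rec_rna$ks_p, 0.05)
    # exactly identical value distributions (a shared grid, repeated in
    # proportion) -> D = 0, ratio 1, direction none
    fc0 <- fc
    grid <- seq(-1, 1, length.out = 40)
    fc0$log2_eff_fc[ids %in% targets] <- rep(grid, 3)        # 120 targets
    fc0$log2_eff_fc[!(ids %in% targets)] <- rep(grid, 72)    # 2880 others
    rec0 <- cross_tissue_target_shift(fc0, targets, metric = "Eff")
    expect_equal(rec0$direction, "none")
    expect_equal(rec0$ks_p, 1)
    expect_equal(rec0$ratio, 1)
  })
})

test_that("stronger-repression fraction recovers the configured tissue bias", {
  withr::with_seed(77, {
    n <- 4000
    ids <- sprintf("g%04d", 1:n)
    base <- stats::setNames(rlnorm(n, log(30), 1), ids)
    n_fam <- 200
    fam_targets <- lapply(1:n_fam, function(i) sample(ids, 60))
    names(fam_targets) <- sprintf("fam%03d", 1:n_fam)
    bat_stronger <- c(rep(TRUE, 150), rep(FALSE, 50))   # 75% bias
    vals_bat <- base
    vals_wat <- base * 2^rnorm(n, 0, 0.1)
    for (i in 1:n_fam) {
      s_weak <- 0.3
      s_strong <- 0.8
      vals_bat <- repress(vals_bat, fam_targets[[i]],
                          if (bat_stronger[i]) s_strong else s_weak)
      vals_wat <- repress(vals_wat, fam_targets[[i]],
                          if (bat_stronger[i]) s_weak else s_strong)
    }
    fams <- data.frame(
      family_id = rep(names(fam_targets), lengths(fam_targets)),
      gene_id = unlist(fam_targets), n_sites = 1L,
      stringsAsFactors = FALSE
    )
    rec_bat <- family_repression_table(vals_bat, fams, "RNA", "BAT")
    rec_wat <- family_repression_table(vals_wat, fams, "RNA", "WAT")
    est <- stronger_repression_fraction(rec_bat, rec_wat)
    expect_false(est$empty)
    expect_lt(abs(est$fraction - 0.75), 0.10)
    # swapping tissues maps the fraction to its complement (ties aside)
    est_swap <- stronger_repression_fraction(rec_wat, rec_bat)
    expect_equal(est$fraction + est_swap$fraction, 1, tolerance = 1e-9)
  })
})

test_that("identical tissues give only ties, reported not counted", {
  vals <- withr::with_seed(18, stats::setNames(rlnorm(500, 3, 1), sprintf("g%03d", 1:500)))
  fams <- data.frame(family_id = "f1", gene_id = names(vals)[1:50],
                     n_sites = 1L, stringsAsFactors = FALSE)
  vals_r <- repress(vals, fams$gene_id, 1)   # make the family significant
  ra <- family_repression_table(vals_r, fams, "RNA", "A")
  rb <- family_repression_table(vals_r, fams, "RNA", "B")
  est <- stronger_repression_fraction(ra, rb)
  expect_equal(est$n_ties, 1)
  expect_true(est$empty)
  expect_true(is.na(est$fraction))
})

test_that("site-density regression finds planted trends and exact nulls", {
  withr::with_seed(30, {
    n <- 2000
    ids <- sprintf("g%04d", 1:n)
    fc <- stats::setNames(rnorm(n), ids)
    # constant site count: every bin mean = k, slope exactly 0
    const_sites <- stats::setNames(rep(3, n), ids)
    res0 <- site_density_vs_fc(fc, const_sites)
    expect_true(all(res0$bins$mean_sites == 3))
    expect_equal(res0$slope, 0)
    # independent sites: slope ~ 0, p not tiny
    rand_sites <- stats::setNames(rpois(n, 2), ids)
    res1 <- site_density_vs_fc(fc, rand_sites)
    expect_gt(res1$slope_p, 0.001)
    # planted negative trend: more sites among down-shifted genes
    dep_sites <- stats::setNames(rpois(n, pmax(0.2, 2 - fc)), ids)
    res2 <- site_density_vs_fc(fc, dep_sites)
    expect_lt(res2$slope, 0)
    expect_lt(res2$slope_p, 0.01)
    expect_error(site_density_vs_fc(fc, rand_sites, n_bins = 1),
                 "invalid-config")
  })
})

test_that("miRNA repression propagates correctly through the simulator", {
  # RNA-metric repression must shift RNA and RPF but leave Eff null
  cfg <- sim_config(n_genes = 2500, n_families = 8, targets_per_family = 120,
                    class_fractions = list(),
                    tissue_bias = 1, repression_base_range = c(0.8, 0.8),
                    repression_diff = 0.7, repression_metric = "RNA",
                    seed = 55)
  exp <- simulate_experiment(cfg)
  kept <- filter_detected(exp$counts)
  rp <- rpkm(subset_expr(exp$counts, genes = kept), exp$ann$genes)
  eff <- translational_efficiency(rp, pseudocount = 0.1)
  fams <- collapse_families(exp$ann$targets)
  sel_rna <- rp$samples$assay == "RNA" & rp$samples$condition == "BAT"
  rna_bat <- rowMeans(rp$mat[, sel_rna, drop = FALSE])
  sel_rpf <- rp$samples$assay == "RPF" & rp$samples$condition == "BAT"
  rpf_bat <- rowMeans(rp$mat[, sel_rpf, drop = FALSE])
  eff_bat <- rowMeans(eff$mat[, grepl("^BAT_", colnames(eff$mat)), drop = FALSE])
  rec_rna <- family_repression_table(rna_bat, fams, "RNA", "BAT")
  rec_rpf <- family_repression_table(rpf_bat, fams, "RPF", "BAT")
  rec_eff <- family_repression_table(eff_bat, fams, "Eff", "BAT")
  expect_true(all(rec_rna$ks_p < 0.01))
  expect_true(all(rec_rpf$ks_p < 0.01))
  expect_true(all(rec_rna$ratio < 1))
  # no translational repression: Eff records mostly null
  expect_gte(sum(rec_eff$ks_p > 0.05), 6)
})
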