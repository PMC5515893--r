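#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic ribosome
#' profiling / RNA-seq experiment. The simulated design mirrors a typical
#' adipocyte translatome study: two in-vitro differentiation lineages (brown
#' and white preadipocytes at day 0 and day 5) plus two directly harvested
#' tissues (BAT, brown adipose; WAT, white adipose), each profiled by paired
#' RPF and RNA-seq libraries in duplicate.
#'
#' Three contrasts are simulated with independent ground-truth regulation:
#' `brown` (BATD5 vs BATD0), `white` (WATD5 vs WATD0) and `tissue`
#' (BAT vs WAT). Within each contrast every gene is assigned one of seven
#' classes: `translation_up/down` (translational-efficiency change only),
#' `rna_up/down` (mRNA-level change only), `synergistic_up/down` (both
#' components, same sign) or `unregulated`. Class allocation is by exact
#' count (`floor(fraction * n_genes)`), not Bernoulli, so expected group
#' sizes are exact.
#'
#' @param n_genes Number of genes (default 5000).
#' @param n_replicates Libraries per condition per assay (default 2).
#' @param class_fractions Named list, one element per contrast
#'   (`brown`, `white`, `tissue`), each a named numeric vector over the six
#'   regulated classes. Fractions in a contrast must sum to <= 1; the
#'   remainder is unregulated. Default: 1/30 per class per contrast
#'   (~1000 regulated genes of 5000, balanced).
#' @param effect_major_range Range (log2) for the driving component of
#'   translation-/RNA-driven classes. Default `c(2, 3)`.
#' @param effect_minor_range Range (log2, absolute) for the passive
#'   component. Default `c(0, 0.4)`.
#' @param effect_syn_range Range (log2) for each component of synergistic
#'   classes. Default `c(1.5, 2.5)`.
#' @param background_rna_sd,background_eff_sd Standard deviation (log2) of
#'   Gaussian background variation added to the RNA / efficiency component of
#'   unregulated genes (default 0: unregulated genes are flat). Useful for
#'   building scenarios with a controlled variance share between components.
#' @param nb_dispersion Negative-binomial dispersion of counts
#'   (variance = mu + dispersion * mu^2). `0` selects the Poisson branch.
#'   Default 0.05, a typical replicate-level value for deeply sequenced
#'   libraries.
#' @param library_size Mapped reads per library (default 1e7, matching a
#'   >10-million-read design).
#' @param n_families Number of microRNA seed families (default 219, the
#'   number of conserved families in standard TargetScan-style resources).
#' @param targets_per_family Conserved targets sampled per family
#'   (default 100).
#' @param site_count_mean Mean conserved sites per (family, target) pair
#'   (>= 1; sites are `1 + Poisson(site_count_mean - 1)`). Default 1.5.
#' @param tissue_bias Fraction of families repressing their targets more
#'   strongly in BAT than WAT (default 0.75).
#' @param repression_metric Which component family repression acts on:
#'   `"RNA"` (mRNA decay; also propagates to RPF) or `"Eff"` (translational
#'   repression). Default `"RNA"`.
#' @param repression_base_range Range (log2 >= 0) of the weaker tissue's
#'   repression strength. Default `c(0.2, 0.4)`.
#' @param repression_diff Extra log2 repression in the stronger tissue
#'   (default 0.5).
#' @param utr5_len,utr3_len Fixed UTR lengths in nt (defaults 100 and 200).
#' @param cds_meanlog,cds_sdlog Log-normal parameters of CDS length
#'   (defaults `log(900)` and 0.4: median CDS ~900 nt).
#' @param baseline_rpkm_meanlog,baseline_rpkm_sdlog Log-normal parameters of
#'   baseline mRNA abundance in RPKM (defaults `log(30)`, 1).
#' @param baseline_eff_meanlog,baseline_eff_sdlog Log-normal parameters of
#'   baseline translational efficiency (defaults 0, 0.5).
#' @param category_fractions Named fractions of genes carrying each
#'   annotation category label.
#' @param seed Integer seed; every generator output is a pure function of
#'   (config, seed).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_replicates = 2,
                       class_fractions = NULL,
                       effect_major_range = c(2, 3),
                       effect_minor_range = c(0, 0.4),
                       effect_syn_range = c(1.5, 2.5),
                       background_rna_sd = 0,
                       background_eff_sd = 0,
                       nb_dispersion = 0.05,
                       library_size = 1e7,
                       n_families = 219,
                       targets_per_family = 100,
                       site_count_mean = 1.5,
                       tissue_bias = 0.75,
                       repression_metric = c("RNA", "Eff"),
                       repression_base_range = c(0.2, 0.4),
                       repression_diff = 0.5,
                       utr5_len = 100,
                       utr3_len = 200,
                       cds_meanlog = log(900),
                       cds_sdlog = 0.4,
                       baseline_rpkm_meanlog = log(30),
                       baseline_rpkm_sdlog = 1,
                       baseline_eff_meanlog = 0,
                       baseline_eff_sdlog = 0.5,
                       category_fractions = c(mitochondrion = 0.05,
                                              lipid_metabolism = 0.05,
                                              translation = 0.04),
                       seed = 1L) {
  repression_metric <- match.arg(repression_metric)
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1) {
    stop_invalid("n_genes must be a positive integer")
  }
  if (n_replicates < 1) stop_invalid("n_replicates must be >= 1")
  if (nb_dispersion < 0) stop_invalid("nb_dispersion must be >= 0")
  if (library_size <= 0) stop_invalid("library_size must be > 0")
  if (n_families < 0 || targets_per_family < 0) {
    stop_invalid("family settings must be non-negative")
  }
  if (site_count_mean < 1) stop_invalid("site_count_mean must be >= 1")
  if (tissue_bias < 0 || tissue_bias > 1) stop_invalid("tissue_bias in [0,1]")
  if (repression_diff < 0 || any(repression_base_range < 0)) {
    stop_invalid("repression strengths must be >= 0 (log2 units)")
  }
  classes <- c("translation_up", "synergistic_up", "rna_up",
               "translation_down", "synergistic_down", "rna_down")
  if (is.null(class_fractions)) {
    one <- stats::setNames(rep(1 / 30, 6L), classes)
    class_fractions <- list(brown = one, white = one, tissue = one)
  }
  contrast_names <- c("brown", "white", "tissue")
  if (!all(names(class_fractions) %in% contrast_names)) {
    stop_invalid("class_fractions names must be among ",
                 paste(contrast_names, collapse = ", "))
  }
  for (cn in names(class_fractions)) {
    fr <- class_fractions[[cn]]
    if (!all(names(fr) %in% classes)) {
      stop_invalid("unknown class in class_fractions$", cn)
    }
    if (any(fr < 0) || sum(fr) > 1 + 1e-12) {
      stop_invalid("class_fractions$", cn, " must be >= 0 and sum to <= 1")
    }
  }
  # component threshold for the default classifier is log2(4)/2 = 1 for the
  # adipogenesis contrasts and log2(2)/2 = 0.5 for the tissue contrast; the
  # default ranges keep minor components below 0.5 and driving components
  # above 1.5 so true classes are identifiable under either threshold
  if (effect_minor_range[2] >= effect_syn_range[1]) {
    stop_invalid("effect_minor_range must lie strictly below effect_syn_range")
  }
  if (effect_major_range[1] <= effect_minor_range[2]) {
    stop_invalid("effect ranges inconsistent with class definitions")
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    class_fractions = class_fractions,
    effect_major_range = effect_major_range,
    effect_minor_range = effect_minor_range,
    effect_syn_range = effect_syn_range,
    background_rna_sd = background_rna_sd,
    background_eff_sd = background_eff_sd,
    nb_dispersion = nb_dispersion, library_size = library_size,
    n_families = as.integer(n_families),
    targets_per_family = as.integer(targets_per_family),
    site_count_mean = site_count_mean, tissue_bias = tissue_bias,
    repression_metric = repression_metric,
    repression_base_range = repression_base_range,
    repression_diff = repression_diff,
    utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
    cds_meanlog = cds_meanlog, cds_sdlog = cds_sdlog,
    baseline_rpkm_meanlog = baseline_rpkm_meanlog,
    baseline_rpkm_sdlog = baseline_rpkm_sdlog,
    baseline_eff_meanlog = baseline_eff_meanlog,
    baseline_eff_sdlog = baseline_eff_sdlog,
    category_fractions = category_fractions,
    seed = as.integer(seed),
    conditions = c("BATD0", "BATD5", "WATD0", "WATD5", "BAT", "WAT"),
    contrasts = list(brown = c(a = "BATD0", b = "BATD5"),
                     white = c(a = "WATD0", b = "WATD5"),
                     tissue = c(a = "WAT", b = "BAT"))
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Generate gene annotation and microRNA target structure
#'
#' Draws per-gene transcript structure (fixed 5'/3' UTR lengths, log-normal
#' CDS length rounded to a codon multiple), assigns annotation categories to
#' configured fractions of genes, and samples conserved microRNA seed-family
#' target sets with per-target site counts.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (data frame: `gene_id`, `utr5_len`,
#'   `cds_len`, `utr3_len`, `categories` semicolon-joined) and `targets`
#'   (data frame: `family_id`, `gene_id`, `n_sites`).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "annotation"), {
    n <- config$n_genes
    gene_id <- sprintf("g%05d", seq_len(n))
    cds_len <- round_to_codon(stats::rlnorm(n, config$cds_meanlog, config$cds_sdlog))
    cats <- rep("", n)
    for (cat in names(config$category_fractions)) {
      k <- floor(config$category_fractions[[cat]] * n)
      idx <- sample.int(n, k)
      cats[idx] <- ifelse(nzchar(cats[idx]), paste(cats[idx], cat, sep = ";"), cat)
    }
    genes <- data.frame(gene_id = gene_id,
                        utr5_len = config$utr5_len,
                        cds_len = cds_len,
                        utr3_len = config$utr3_len,
                        categories = cats,
                        stringsAsFactors = FALSE)
    targets <- NULL
    if (config$n_families > 0 && config$targets_per_family > 0) {
      fam_id <- sprintf("fam%03d", seq_len(config$n_families))
      tg <- lapply(seq_len(config$n_families), function(i) {
        tgt <- sample(gene_id, min(config$targets_per_family, n))
        data.frame(family_id = fam_id[i], gene_id = tgt,
                   n_sites = 1L + stats::rpois(length(tgt), config$site_count_mean - 1),
                   stringsAsFactors = FALSE)
      })
      targets <- do.call(rbind, tg)
    } else {
      targets <- data.frame(family_id = character(), gene_id = character(),
                            n_sites = integer(), stringsAsFactors = FALSE)
    }
    list(genes = genes, targets = targets)
  })
}

#' Gene category membership as a list
#'
#' @param genes Annotation data frame from [generate_annotation()].
#' @return Named list: category -> character vector of gene ids.
#' @export
category_sets <- function(genes) {
  has <- nzchar(genes$categories)
  pairs <- strsplit(genes$categories[has], ";", fixed = TRUE)
  ids <- rep(genes$gene_id[has], lengths(pairs))
  split(ids, unlist(pairs))
}

#' Generate ground-truth regulation
#'
#' Allocates regulation classes per contrast by exact count in a seeded
#' random gene order, draws log2 effect sizes inside the class-specific
#' ranges, assigns per-family tissue-specific repression strengths, and
#' accumulates everything into per-condition log2 offsets for the RNA and
#' translational-efficiency components. The additive identity
#' log2 RPF FC = log2 RNA FC + log2 Eff FC holds exactly by construction.
#'
#' @param ann Output of [generate_annotation()].
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` with elements:
#'   `effects` (named list per contrast: data frame `gene_id`, `class`,
#'   `log2_rna_fc`, `log2_eff_fc`, `log2_rpf_fc`), `rna_offset` and
#'   `eff_offset` (gene x condition matrices of absolute log2 offsets),
#'   `families` (data frame `family_id`, `strength_BAT`, `strength_WAT`,
#'   `metric`), and `baseline` (data frame `gene_id`, `baseline_rna_rpkm`,
#'   `baseline_eff`).
#' @export
generate_truth <- function(ann, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- ann$genes
  n <- nrow(genes)
  with_seed(derive_seed(config$seed, "truth"), {
    baseline <- data.frame(
      gene_id = genes$gene_id,
      baseline_rna_rpkm = stats::rlnorm(n, config$baseline_rpkm_meanlog,
                                        config$baseline_rpkm_sdlog),
      baseline_eff = stats::rlnorm(n, config$baseline_eff_meanlog,
                                   config$baseline_eff_sdlog),
      stringsAsFactors = FALSE
    )
    conds <- config$conditions
    rna_off <- matrix(0, n, length(conds), dimnames = list(genes$gene_id, conds))
    eff_off <- matrix(0, n, length(conds), dimnames = list(genes$gene_id, conds))
    effects <- list()
    for (cn in names(config$contrasts)) {
      fr <- config$class_fractions[[cn]] %||% numeric(0)
      cls <- rep("unregulated", n)
      ord <- sample.int(n)                  # seeded random allocation order
      pos <- 1L
      for (k in names(fr)) {
        cnt <- floor(fr[[k]] * n)
        if (cnt > 0) {
          cls[ord[pos:(pos + cnt - 1L)]] <- k
          pos <- pos + cnt
        }
      }
      draw <- function(m, range) stats::runif(m, range[1], range[2])
      a <- numeric(n)  # log2 RNA component
      b <- numeric(n)  # log2 Eff component
      for (k in names(fr)) {
        idx <- which(cls == k)
        m <- length(idx)
        if (!m) next
        sgn <- if (grepl("_down$", k)) -1 else 1
        if (startsWith(k, "translation")) {
          b[idx] <- sgn * draw(m, config$effect_major_range)
          a[idx] <- sample(c(-1, 1), m, TRUE) * draw(m, config$effect_minor_range)
        } else if (startsWith(k, "rna")) {
          a[idx] <- sgn * draw(m, config$effect_major_range)
          b[idx] <- sample(c(-1, 1), m, TRUE) * draw(m, config$effect_minor_range)
        } else { # synergistic: both components above threshold, same sign
          a[idx] <- sgn * draw(m, config$effect_syn_range)
          b[idx] <- sgn * draw(m, config$effect_syn_range)
        }
      }
      unreg <- which(cls == "unregulated")
      if (config$background_rna_sd > 0) {
        a[unreg] <- stats::rnorm(length(unreg), 0, config$background_rna_sd)
      }
      if (config$background_eff_sd > 0) {
        b[unreg] <- stats::rnorm(length(unreg), 0, config$background_eff_sd)
      }
      effects[[cn]] <- data.frame(gene_id = genes$gene_id, class = cls,
                                  log2_rna_fc = a, log2_eff_fc = b,
                                  log2_rpf_fc = a + b,
                                  stringsAsFactors = FALSE)
      ctr <- config$contrasts[[cn]]
      rna_off[, ctr[["b"]]] <- rna_off[, ctr[["b"]]] + a
      eff_off[, ctr[["b"]]] <- eff_off[, ctr[["b"]]] + b
    }
    # per-family tissue-specific repression, applied to the BAT/WAT offsets
    families <- data.frame(family_id = character(), strength_BAT = numeric(),
                           strength_WAT = numeric(), metric = character(),
                           stringsAsFactors = FALSE)
    if (nrow(ann$targets)) {
      fam_ids <- unique(ann$targets$family_id)
      nf <- length(fam_ids)
      weak <- stats::runif(nf, config$repression_base_range[1],
                           config$repression_base_range[2])
      strong <- weak + config$repression_diff
      n_bat <- floor(config$tissue_bias * nf)
      bat_stronger <- c(rep(TRUE, n_bat), rep(FALSE, nf - n_bat))
      bat_stronger <- bat_stronger[sample.int(nf)]
      families <- data.frame(
        family_id = fam_ids,
        strength_BAT = ifelse(bat_stronger, strong, weak),
        strength_WAT = ifelse(bat_stronger, weak, strong),
        metric = config$repression_metric,
        stringsAsFactors = FALSE
      )
      tgt_split <- split(ann$targets$gene_id, ann$targets$family_id)
      for (i in seq_len(nf)) {
        tg <- tgt_split[[fam_ids[i]]]
        if (config$repression_metric == "RNA") {
          rna_off[tg, "BAT"] <- rna_off[tg, "BAT"] - families$strength_BAT[i]
          rna_off[tg, "WAT"] <- rna_off[tg, "WAT"] - families$strength_WAT[i]
        } else {
          eff_off[tg, "BAT"] <- eff_off[tg, "BAT"] - families$strength_BAT[i]
          eff_off[tg, "WAT"] <- eff_off[tg, "WAT"] - families$strength_WAT[i]
        }
      }
    }
    structure(list(effects = effects, rna_offset = rna_off,
                   eff_offset = eff_off, families = families,
                   baseline = baseline),
              class = "sim_truth")
  })
}

#' Simulate paired RPF and RNA-seq count matrices
#'
#' Draws raw counts for every (condition, replicate, assay) library. The RNA
#' mean is baseline abundance x condition effect x CDS length x library
#' depth; the RPF mean additionally carries the baseline translational
#' efficiency and the condition's efficiency effect. Counts are negative
#' binomial with the configured dispersion (Poisson when dispersion is 0);
#' replicates are independent draws.
#'
#' @param truth A `sim_truth` from [generate_truth()].
#' @param ann Output of [generate_annotation()].
#' @param config A [sim_config()].
#' @return An [expr_set()] of raw counts over all conditions, assays and
#'   replicates.
#' @export
simulate_counts <- function(truth, ann, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (config$library_size <= 0) stop_invalid("library_size must be > 0")
  genes <- ann$genes
  n <- nrow(genes)
  conds <- config$conditions
  with_seed(derive_seed(config$seed, "counts"), {
    cds_kb <- genes$cds_len / 1000
    depth <- config$library_size / 1e6
    draw <- function(mu) {
      if (config$nb_dispersion == 0) {
        stats::rpois(length(mu), mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
      }
    }
    cols <- list()
    meta <- list()
    for (cond in conds) {
      mu_rna <- truth$baseline$baseline_rna_rpkm * 2^truth$rna_offset[, cond] *
        cds_kb * depth
      mu_rpf <- mu_rna * truth$baseline$baseline_eff * 2^truth$eff_offset[, cond]
      for (assay in c("RPF", "RNA")) {
        mu <- if (assay == "RPF") mu_rpf else mu_rna
        for (r in seq_len(config$n_replicates)) {
          cols[[length(cols) + 1L]] <- draw(mu)
          meta[[length(meta) + 1L]] <- data.frame(assay = assay,
                                                  condition = cond,
                                                  replicate = r,
                                                  stringsAsFactors = FALSE)
        }
      }
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- genes$gene_id
    expr_set(mat, do.call(rbind, meta), unit = "counts")
  })
}

#' Simulate per-position 5'-end footprint counts for one gene
#'
#' In RPF mode, ribosome P-sites are placed on CDS codons with configurable
#' pause multipliers at the start and stop codons and a within-codon frame
#' weight vector; the recorded 5'-end position is the P-site minus the fixed
#' P-site offset (reads whose 5' end would fall before the transcript start
#' are dropped). In RNA mode, 5' ends are uniform over the full transcript
#' including UTRs, with no frame structure.
#'
#' @param gene One row of the annotation data frame (`utr5_len`, `cds_len`,
#'   `utr3_len`).
#' @param n_reads Number of reads to place (>= 0).
#' @param pause_start,pause_stop Density multipliers (>= 1) at the start and
#'   stop codon (defaults 10 and 6, typical initiation/termination pile-ups).
#' @param frame_weights Probability over codon positions 0..2 for the P-site
#'   frame; must sum to 1 (tolerance 1e-9). Default `c(0.7, 0.15, 0.15)`.
#' @param mode `"RPF"` (CDS-confined, framed, paused) or `"RNA"` (uniform).
#' @param psite_offset Offset (nt) from 5' end to P-site; default 14.
#' @param seed Integer seed.
#' @return Integer vector of 5'-end counts, one entry per transcript
#'   position (0-based; element `i` is position `i - 1`).
#' @export
simulate_footprint_positions <- function(gene, n_reads,
                                         pause_start = 10, pause_stop = 6,
                                         frame_weights = c(0.7, 0.15, 0.15),
                                         mode = c("RPF", "RNA"),
                                         psite_offset = 14L,
                                         seed = 1L) {
  mode <- match.arg(mode)
  if (n_reads < 0) stop_invalid("n_reads must be >= 0")
  if (pause_start < 1 || pause_stop < 1) stop_invalid("pause multipliers must be >= 1")
  if (length(frame_weights) != 3L || abs(sum(frame_weights) - 1) > 1e-9) {
    stop_invalid("frame_weights must be 3 values summing to 1")
  }
  total_len <- gene$utr5_len + gene$cds_len + gene$utr3_len
  out <- integer(total_len)
  if (n_reads == 0) return(out)
  with_seed(seed, {
    if (mode == "RNA") {
      pos <- sample.int(total_len, n_reads, replace = TRUE) - 1L
    } else {
      n_codons <- gene$cds_len %/% 3L
      codon_w <- rep(1, n_codons)
      codon_w[1] <- pause_start
      codon_w[n_codons] <- pause_stop
      codon <- sample.int(n_codons, n_reads, replace = TRUE, prob = codon_w) - 1L
      frame <- sample.int(3L, n_reads, replace = TRUE, prob = frame_weights) - 1L
      psite <- gene$utr5_len + 3L * codon + frame
      pos <- psite - as.integer(psite_offset)
      pos <- pos[pos >= 0L]          # reads whose 5' end precedes the transcript
    }
    tb <- tabulate(pos + 1L, nbins = total_len)
    out <- as.integer(tb)
  })
  out
}

#' Run the full generator and write its artifacts
#'
#' Convenience wrapper: annotation, truth, counts, and (optionally)
#' positional footprints for a subset of genes, written as the TSV formats
#' consumed by the downstream modules.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param n_footprint_genes Number of genes to simulate positional
#'   footprints for (default 0 = skip).
#' @param footprint_reads Reads per footprint gene (default 2000).
#' @return A list with `ann`, `truth`, `counts` and (if requested)
#'   `footprints` (data frame `gene_id`, `position`, `count`), plus `files`
#'   naming anything written.
#' @export
simulate_experiment <- function(config, outdir = NULL,
                                n_footprint_genes = 0,
                                footprint_reads = 2000) {
  ann <- generate_annotation(config)
  truth <- generate_truth(ann, config)
  counts <- simulate_counts(truth, ann, config)
  fp <- NULL
  if (n_footprint_genes > 0) {
    idx <- seq_len(min(n_footprint_genes, nrow(ann$genes)))
    fp_list <- lapply(idx, function(i) {
      g <- ann$genes[i, ]
      v <- simulate_footprint_positions(g, footprint_reads,
                                        seed = derive_seed(config$seed,
                                                           paste0("fp", i)))
      nz <- which(v > 0L)
      if (!length(nz)) return(NULL)
      data.frame(gene_id = g$gene_id, position = nz - 1L, count = v[nz],
                 stringsAsFactors = FALSE)
    })
    fp <- do.call(rbind, fp_list)
  }
  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_tsv(ann$genes, p("annotation.tsv"))
    write_tsv(ann$targets, p("targets.tsv"))
    write_expr_set(counts, p("counts.tsv"))
    truth_df <- do.call(rbind, lapply(names(truth$effects), function(cn) {
      cbind(contrast = cn, truth$effects[[cn]])
    }))
    write_tsv(truth_df, p("truth.tsv"))
    files <- c(annotation = p("annotation.tsv"), targets = p("targets.tsv"),
               counts = p("counts.tsv"), truth = p("truth.tsv"))
    if (!is.null(fp)) {
      write_tsv(fp, p("footprints.tsv"))
      files <- c(files, footprints = p("footprints.tsv"))
    }
  }
  list(ann = ann, truth = truth, counts = counts, footprints = fp,
       files = files)
}
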