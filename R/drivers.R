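# Decomposition of ribosome-footprint (RPF) fold changes into their mRNA
# (RNA) and translational-efficiency (Eff) components. Because
# Eff = RPF_RPKM / RNA_RPKM, log2 fold changes obey the additive identity
# log2 FC(Eff) = log2 FC(RPF) - log2 FC(RNA); the Eff fold change is always
# computed from that identity so it holds to machine precision.

#' Per-gene fold changes between two conditions
#'
#' Computes log2 fold changes of RNA, RPF and Eff between condition `a`
#' (denominator) and condition `b` (numerator). Each assay's fold change is
#' `(mean_b + pseudocount) / (mean_a + pseudocount)` on replicate-averaged
#' RPKM; the Eff fold change is the difference of the RPF and RNA log2 fold
#' changes.
#'
#' @param rpkm_es An [expr_set()] in RPKM containing both assays and both
#'   conditions.
#' @param cond_a,cond_b Condition labels (a = reference/denominator).
#' @param pseudocount Added to numerator and denominator means (default
#'   0.5, stabilising fold changes of weakly expressed genes).
#' @param replicates Optional integer vector: use only these replicate
#'   numbers (for replicate-level fold changes feeding
#'   [contribution_ratio()]).
#' @param normalize `"none"` (default) leaves the raw RPKM fold changes;
#'   `"median"` centres each assay's log2 fold changes on their per-assay
#'   median (median-of-ratios style). RPKM divides by the realized library
#'   total, so when many genes change in one linear direction every fold
#'   change inherits a composition shift; median centring removes it under
#'   the usual assumption that most genes are unregulated. The Eff fold
#'   change is recomputed as RPF minus RNA, preserving the decomposition
#'   identity exactly.
#' @return Data frame of class `fc_table`: `gene_id`, `log2_rna_fc`,
#'   `log2_rpf_fc`, `log2_eff_fc`; attributes `contrast`, `pseudocount` and
#'   `normalize`.
#' @export
fold_changes <- function(rpkm_es, cond_a, cond_b, pseudocount = 0.5,
                         replicates = NULL,
                         normalize = c("none", "median")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(rpkm_es, "expr_set"))
  if (rpkm_es$unit != "RPKM") stop("wrong-unit: fold_changes requires RPKM", call. = FALSE)
  s <- rpkm_es$samples
  mean_assay <- function(assay, cond) {
    sel <- s$assay == assay & s$condition == cond
    if (!is.null(replicates)) sel <- sel & s$replicate %in% replicates
    if (!any(sel)) {
      stop("pairing error: no ", assay, " libraries for condition ", cond,
           call. = FALSE)
    }
    rowMeans(rpkm_es$mat[, sel, drop = FALSE])
  }
  l2 <- function(assay) {
    a <- mean_assay(assay, cond_a)
    b <- mean_assay(assay, cond_b)
    log2((b + pseudocount) / (a + pseudocount))
  }
  rna <- l2("RNA")
  rpf <- l2("RPF")
  if (normalize == "median") {
    rna <- rna - stats::median(rna)
    rpf <- rpf - stats::median(rpf)
  }
  out <- data.frame(gene_id = rownames(rpkm_es$mat),
                    log2_rna_fc = rna, log2_rpf_fc = rpf,
                    log2_eff_fc = rpf - rna,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- paste0(cond_b, "_vs_", cond_a)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "normalize") <- normalize
  class(out) <- c("fc_table", "data.frame")
  out
}

#' Classify regulated genes by the driver of their RPF change
#'
#' Genes whose RPF fold change passes the threshold are partitioned into
#' six groups by the relative contribution of the RNA and Eff components:
#' groups 1-3 are up-regulated (1 translation-driven, 2 synergistic, 3
#' RNA-driven), groups 4-6 the same for down-regulation. With
#' `a = log2 RNA FC`, `b = log2 Eff FC` and component threshold `c`:
#' translation-driven if `|a| < c`, RNA-driven if `|b| < c`, synergistic if
#' both exceed `c` with the same sign; when both exceed `c` with opposite
#' signs the larger-magnitude component wins (tie: RNA-driven). The default
#' `c = log2(threshold)/2` makes the partition exhaustive.
#'
#' @param fc An `fc_table` from [fold_changes()].
#' @param rpf_fold_threshold Linear fold-change threshold on RPF
#'   (default 4; use 2 for tissue-level contrasts).
#' @param component_threshold Log2 threshold separating active from passive
#'   components (default `log2(rpf_fold_threshold) / 2`).
#' @return Data frame: `gene_id`, `group` (1-6), `category`
#'   (`translation_driven` / `synergistic` / `rna_driven`), `direction`
#'   (`up` / `down`), plus the three log2 fold changes. Genes below the RPF
#'   threshold are absent.
#' @export
classify_drivers <- function(fc, rpf_fold_threshold = 4,
                             component_threshold = log2(rpf_fold_threshold) / 2) {
  if (rpf_fold_threshold <= 1) stop_invalid("rpf_fold_threshold must be > 1")
  if (component_threshold <= 0) stop_invalid("component_threshold must be > 0")
  lt <- log2(rpf_fold_threshold)
  sel <- abs(fc$log2_rpf_fc) >= lt
  sub <- fc[sel, , drop = FALSE]
  a <- sub$log2_rna_fc
  b <- sub$log2_eff_fc
  cthr <- component_threshold
  category <- character(nrow(sub))
  small_a <- abs(a) < cthr
  small_b <- abs(b) < cthr
  category[small_a] <- "translation_driven"
  category[!small_a & small_b] <- "rna_driven"
  both <- !small_a & !small_b
  same_sign <- both & sign(a) == sign(b)
  category[same_sign] <- "synergistic"
  conflict <- both & sign(a) != sign(b)
  # opposite-sign components: the larger magnitude names the driver
  category[conflict & abs(b) > abs(a)] <- "translation_driven"
  category[conflict & abs(b) <= abs(a)] <- "rna_driven"
  direction <- ifelse(sub$log2_rpf_fc > 0, "up", "down")
  base <- match(category, c("translation_driven", "synergistic", "rna_driven"))
  group <- base + ifelse(direction == "down", 3L, 0L)
  out <- data.frame(gene_id = sub$gene_id, group = group,
                    category = category, direction = direction,
                    log2_rna_fc = a, log2_rpf_fc = sub$log2_rpf_fc,
                    log2_eff_fc = b,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "rpf_fold_threshold") <- rpf_fold_threshold
  attr(out, "component_threshold") <- component_threshold
  out
}

#' Summarise driver classes
#'
#' Collapses the six groups into the three driver categories
#' (translation-driven = groups 1+4, synergistic = 2+5, RNA-driven = 3+6)
#' and reports counts and percentages of the classified total.
#'
#' @param x Either a classification data frame from [classify_drivers()]
#'   or a numeric vector of six per-group counts (groups 1..6).
#' @return A list: `counts` (named, the three categories), `percent`
#'   (named, to one decimal), `total`. When nothing is classified, `empty`
#'   is `TRUE`.
#' @examples
#' summarize_driver_classes(c(4, 54, 331, 107, 203, 260))
#' @export
summarize_driver_classes <- function(x) {
  cats <- c("translation_driven", "synergistic", "rna_driven")
  if (is.data.frame(x)) {
    grp <- tabulate(x$group, nbins = 6L)
  } else {
    if (length(x) != 6L || any(x < 0)) {
      stop("summarize_driver_classes: need 6 non-negative group counts",
           call. = FALSE)
    }
    grp <- as.numeric(x)
  }
  counts <- stats::setNames(grp[1:3] + grp[4:6], cats)
  total <- sum(counts)
  if (total == 0) {
    return(list(counts = counts, percent = stats::setNames(rep(NA_real_, 3), cats),
                total = 0, empty = TRUE))
  }
  list(counts = counts,
       percent = round(100 * counts / total, 1),
       total = total, empty = FALSE)
}

#' Relative contribution of Eff vs RNA to RPF fold changes
#'
#' Estimates how much of the between-condition RPF change is attributable
#' to translational-efficiency change versus mRNA change, using the ratio
#' of correlations between variables to the correlation between
#' experimental duplicates as the noise ceiling: `r_rep` is the correlation
#' of the two replicate-level estimates of the RPF fold change, while
#' `r_eff` and `r_rna` correlate the replicate-averaged Eff and RNA fold
#' changes with the replicate-averaged RPF fold change. The Eff share is
#' `100 * (r_eff/r_rep) / (r_eff/r_rep + r_rna/r_rep)` when both ratios are
#' positive.
#'
#' @param fc_rep1,fc_rep2 `fc_table`s computed from replicate 1 only and
#'   replicate 2 only (same genes, same contrast).
#' @param fc_avg Optional replicate-averaged `fc_table`; defaults to the
#'   mean of the two replicate tables.
#' @return A list of class `contribution_estimate`: `r_rep`, `r_rna`,
#'   `r_eff`, `ratio_rna`, `ratio_eff`, `eff_contribution_pct`,
#'   `rna_contribution_pct`, `reliable` (FALSE when `r_rep <= 0`).
#' @export
contribution_ratio <- function(fc_rep1, fc_rep2, fc_avg = NULL) {
  if (!identical(fc_rep1$gene_id, fc_rep2$gene_id)) {
    stop("contribution_ratio: replicate tables must cover the same genes",
         call. = FALSE)
  }
  r_rep <- stats::cor(fc_rep1$log2_rpf_fc, fc_rep2$log2_rpf_fc)
  if (is.null(fc_avg)) {
    fc_avg <- fc_rep1
    for (col in c("log2_rna_fc", "log2_rpf_fc", "log2_eff_fc")) {
      fc_avg[[col]] <- (fc_rep1[[col]] + fc_rep2[[col]]) / 2
    }
  }
  r_rna <- stats::cor(fc_avg$log2_rna_fc, fc_avg$log2_rpf_fc)
  r_eff <- stats::cor(fc_avg$log2_eff_fc, fc_avg$log2_rpf_fc)
  out <- list(r_rep = r_rep, r_rna = r_rna, r_eff = r_eff,
              ratio_rna = r_rna / r_rep, ratio_eff = r_eff / r_rep,
              eff_contribution_pct = NA_real_,
              rna_contribution_pct = NA_real_,
              reliable = is.finite(r_rep) && r_rep > 0)
  if (!out$reliable) {
    warning("unreliable-estimate: replicate correlation r_rep <= 0")
    class(out) <- "contribution_estimate"
    return(out)
  }
  re <- max(out$ratio_eff, 0)
  rr <- max(out$ratio_rna, 0)
  if (re + rr > 0) {
    out$eff_contribution_pct <- 100 * re / (re + rr)
    out$rna_contribution_pct <- 100 * rr / (re + rr)
  }
  class(out) <- "contribution_estimate"
  out
}

#' Rank genes by differential translational-efficiency change
#'
#' Ranks genes by the difference of their Eff fold changes between two
#' contrasts (e.g. brown minus white adipogenesis):
#' `key = log2_eff_fc(contrast1) - log2_eff_fc(contrast2)`, in log2 space
#' equivalent to the ratio of the two linear Eff fold changes. Descending
#' order; ties broken by gene id.
#'
#' @param fc_contrast1,fc_contrast2 `fc_table`s over the same gene set.
#' @return Data frame `gene_id`, `delta_eff` sorted descending, with the
#'   ranking also available as the row order.
#' @export
delta_eff_ranking <- function(fc_contrast1, fc_contrast2) {
  if (!setequal(fc_contrast1$gene_id, fc_contrast2$gene_id)) {
    stop("delta_eff_ranking: contrasts must share the gene set", call. = FALSE)
  }
  m <- match(fc_contrast1$gene_id, fc_contrast2$gene_id)
  key <- fc_contrast1$log2_eff_fc - fc_contrast2$log2_eff_fc[m]
  ord <- order(-key, fc_contrast1$gene_id)
  data.frame(gene_id = fc_contrast1$gene_id[ord], delta_eff = key[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}
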