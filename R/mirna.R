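# Systematic per-microRNA-family target repression analysis. MicroRNAs
# sharing a seed sequence target the same mRNAs, so member microRNAs are
# collapsed into seed families before testing; each family's conserved
# targets are then compared with all other analysed genes (non-targets) by
# cumulative-distribution (KS) shift tests at the RNA, RPF and Eff levels.

#' Collapse microRNA members into seed families
#'
#' @param target_table Data frame with columns `mirna_id` (or `family_id`),
#'   `gene_id`, `n_sites`.
#' @param family_map Optional data frame `mirna_id`, `family_id`; unmapped
#'   ids become singleton families named after themselves.
#' @return Data frame `family_id`, `gene_id`, `n_sites` with one row per
#'   (family, target): targets are the union over members, the site count
#'   the per-gene maximum over members. Rows are sorted by family then gene.
#' @export
collapse_families <- function(target_table, family_map = NULL) {
  if (!nrow(target_table)) stop("collapse_families: empty target table", call. = FALSE)
  tt <- as.data.frame(target_table, stringsAsFactors = FALSE)
  if (!"mirna_id" %in% names(tt)) {
    if ("family_id" %in% names(tt)) tt$mirna_id <- tt$family_id else
      stop("collapse_families: need a mirna_id or family_id column", call. = FALSE)
  }
  fam <- tt$mirna_id
  if (!is.null(family_map)) {
    m <- match(tt$mirna_id, family_map$mirna_id)
    fam[!is.na(m)] <- family_map$family_id[m[!is.na(m)]]
  }
  agg <- stats::aggregate(n_sites ~ family_id + gene_id,
                          data = data.frame(family_id = fam,
                                            gene_id = tt$gene_id,
                                            n_sites = tt$n_sites,
                                            stringsAsFactors = FALSE),
                          FUN = max)
  agg <- agg[order(agg$family_id, agg$gene_id), c("family_id", "gene_id", "n_sites")]
  rownames(agg) <- NULL
  agg
}

# split a collapsed target table into a named list of target-gene vectors
family_target_sets <- function(families) {
  split(families$gene_id, families$family_id)
}

#' Within-tissue target repression test for one family
#'
#' Compares a family's conserved targets with all other analysed genes on
#' one expression metric within one tissue. The KS test runs on
#' `log2(value + 1)`; the effect size is the ratio of linear-scale means
#' (targets / non-targets), so repression corresponds to ratio < 1 with a
#' significant KS p.
#'
#' @param values Named numeric vector of linear-scale values (e.g. RPKM or
#'   Eff) over the analysed genes.
#' @param targets Character vector: the family's target gene ids.
#' @param family_id Family label carried into the record.
#' @param metric Metric label (`"RNA"`, `"RPF"` or `"Eff"`).
#' @param tissue Tissue/condition label.
#' @param min_targets Minimum detected targets to test (default 10).
#' @return One-row data frame (`family_id`, `metric`, `tissue`,
#'   `n_targets`, `ratio`, `ks_p`, `direction`, `repressed`, `skipped`).
#' @export
target_repression_within_tissue <- function(values, targets, family_id = NA,
                                            metric = NA, tissue = NA,
                                            min_targets = 10) {
  inset <- names(values) %in% targets
  n_t <- sum(inset)
  if (n_t < min_targets) {
    return(data.frame(family_id = family_id, metric = metric, tissue = tissue,
                      n_targets = n_t, ratio = NA_real_, ks_p = NA_real_,
                      direction = NA_character_, repressed = NA,
                      skipped = TRUE, stringsAsFactors = FALSE))
  }
  ks <- set_shift_test(log2(values + 1), targets,
                       background_mode = "all_other_genes")
  ratio <- mean(values[inset]) / mean(values[!inset])
  data.frame(family_id = family_id, metric = metric, tissue = tissue,
             n_targets = n_t, ratio = ratio, ks_p = ks$p_value,
             direction = ks$shift_direction,
             repressed = ratio < 1 & ks$p_value < 0.05,
             skipped = FALSE, stringsAsFactors = FALSE)
}

#' Cross-tissue target fold-change shift for one family
#'
#' Compares targets' and non-targets' between-tissue log2 fold changes by
#' KS; the effect size is the ratio of mean linear fold changes
#' (targets / non-targets). A left shift on a BAT-vs-WAT contrast means the
#' family represses its targets more strongly in BAT.
#'
#' @param fc An `fc_table` (e.g. BAT vs WAT).
#' @param targets Character vector of target gene ids.
#' @param metric Which fold change to use: `"RNA"`, `"RPF"` or `"Eff"`.
#' @param family_id Family label.
#' @param min_targets Minimum detected targets (default 10).
#' @return One-row data frame as in [target_repression_within_tissue()],
#'   with `tissue` set to the contrast label.
#' @export
cross_tissue_target_shift <- function(fc, targets, metric = c("RNA", "RPF", "Eff"),
                                      family_id = NA, min_targets = 10) {
  metric <- match.arg(metric)
  col <- c(RNA = "log2_rna_fc", RPF = "log2_rpf_fc", Eff = "log2_eff_fc")[[metric]]
  values <- stats::setNames(fc[[col]], fc$gene_id)
  inset <- names(values) %in% targets
  n_t <- sum(inset)
  contrast <- attr(fc, "contrast") %||% "contrast"
  if (n_t < min_targets) {
    return(data.frame(family_id = family_id, metric = metric, tissue = contrast,
                      n_targets = n_t, ratio = NA_real_, ks_p = NA_real_,
                      direction = NA_character_, repressed = NA,
                      skipped = TRUE, stringsAsFactors = FALSE))
  }
  ks <- set_shift_test(values, targets, background_mode = "all_other_genes")
  ratio <- mean(2^values[inset]) / mean(2^values[!inset])
  data.frame(family_id = family_id, metric = metric, tissue = contrast,
             n_targets = n_t, ratio = ratio, ks_p = ks$p_value,
             direction = ks$shift_direction,
             repressed = ratio < 1 & ks$p_value < 0.05,
             skipped = FALSE, stringsAsFactors = FALSE)
}

#' Repression records for all families on one metric in one tissue
#'
#' @param values Named numeric vector (linear scale) for the tissue/metric.
#' @param families Collapsed target table from [collapse_families()].
#' @param metric,tissue Labels carried into the records.
#' @param min_targets Minimum detected targets per family.
#' @return Data frame with one row per family.
#' @export
family_repression_table <- function(values, families, metric, tissue,
                                    min_targets = 10) {
  sets <- family_target_sets(families)
  rows <- lapply(names(sets), function(f) {
    target_repression_within_tissue(values, sets[[f]], family_id = f,
                                    metric = metric, tissue = tissue,
                                    min_targets = min_targets)
  })
  do.call(rbind, rows)
}

#' Fraction of families repressing more strongly in one tissue
#'
#' For families whose targets are significantly repressed in at least one of
#' the two tissues, reports the fraction whose target/non-target ratio is
#' smaller (more repressed) in the first tissue. Exact ties are excluded
#' from both numerator and denominator and reported.
#'
#' @param records_a,records_b Matched records (same families, same metric)
#'   from [family_repression_table()] for the two tissues; the fraction
#'   refers to stronger repression in `records_a`'s tissue.
#' @param require_significant Restrict to families significant
#'   (`repressed`) in at least one tissue (default TRUE).
#' @return A list: `fraction`, `n_eligible`, `n_stronger_a`, `n_ties`,
#'   `empty` flag.
#' @export
stronger_repression_fraction <- function(records_a, records_b,
                                         require_significant = TRUE) {
  m <- match(records_a$family_id, records_b$family_id)
  if (anyNA(m)) stop("stronger_repression_fraction: family lists differ", call. = FALSE)
  b <- records_b[m, ]
  ok <- !records_a$skipped & !b$skipped
  if (require_significant) {
    ok <- ok & (records_a$repressed | b$repressed)
  }
  if (!any(ok)) {
    return(list(fraction = NA_real_, n_eligible = 0, n_stronger_a = 0,
                n_ties = 0, empty = TRUE))
  }
  ra <- records_a$ratio[ok]
  rb <- b$ratio[ok]
  ties <- ra == rb
  n_elig <- sum(!ties)
  n_a <- sum(ra < rb)
  list(fraction = if (n_elig > 0) n_a / n_elig else NA_real_,
       n_eligible = n_elig, n_stronger_a = n_a, n_ties = sum(ties),
       empty = n_elig == 0)
}

#' Binding-site density along the fold-change axis
#'
#' Ranks genes by a fold change, splits them into equal-size rank bins, and
#' regresses the per-bin mean total conserved site count on the bin index
#' by ordinary least squares. A negative slope on an Eff or RPF fold-change
#' binning indicates that down-shifted genes harbour more microRNA binding
#' sites. Rank ties are broken by gene id.
#'
#' @param fc_values Named numeric vector (gene -> fold change, log2).
#' @param site_totals Named numeric vector (gene -> total conserved sites
#'   over all families; genes absent default to 0).
#' @param n_bins Number of rank bins (default 20).
#' @return A list: `bins` (data frame `bin`, `mean_sites`, `n_genes`),
#'   `slope`, `intercept`, `slope_p`.
#' @export
site_density_vs_fc <- function(fc_values, site_totals, n_bins = 20) {
  if (n_bins < 2) stop_invalid("n_bins must be >= 2")
  n <- length(fc_values)
  if (n < n_bins) stop("site_density_vs_fc: fewer genes than bins", call. = FALSE)
  ord <- order(fc_values, names(fc_values))
  sites <- site_totals[names(fc_values)[ord]]
  sites[is.na(sites)] <- 0
  bin <- as.integer(cut(seq_len(n), breaks = n_bins, labels = FALSE))
  bins <- data.frame(bin = seq_len(n_bins),
                     mean_sites = as.numeric(tapply(sites, bin, mean)),
                     n_genes = as.integer(table(bin)))
  fit <- stats::lm(mean_sites ~ bin, data = bins)
  co <- suppressWarnings(summary(fit)$coefficients)  # constant input: perfect fit
  list(bins = bins, slope = unname(co["bin", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       slope_p = unname(co["bin", "Pr(>|t|)"]))
}

#' Total conserved sites per gene
#'
#' @param families Collapsed target table from [collapse_families()].
#' @param gene_ids Genes to report (absent genes get 0).
#' @return Named numeric vector of summed site counts across families.
#' @export
total_site_counts <- function(families, gene_ids) {
  s <- tapply(families$n_sites, families$gene_id, sum)
  out <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
  hit <- intersect(names(s), gene_ids)
  out[hit] <- s[hit]
  out
}
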