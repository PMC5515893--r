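#' Detection filter on raw counts
#'
#' Keeps genes covered by at least `min_reads` raw reads in both the
#' ribosome-profiling and the RNA-seq assay. Coverage is assessed per
#' condition on the replicate-pooled count (the sum over replicates within
#' each condition must reach `min_reads` for each assay, in every condition
#' considered), producing a single analysis gene list.
#'
#' @param counts An [expr_set()] of raw counts.
#' @param min_reads Minimum pooled raw reads per assay per condition
#'   (default 10).
#' @param conditions Conditions over which the filter applies (default: all
#'   conditions present).
#' @return Character vector of retained gene ids, in input order.
#' @examples
#' m <- matrix(c(12, 9, 50, 0, 10,  15, 50, 9, 0, 10), ncol = 2,
#'             dimnames = list(paste0("g", 1:5), NULL))
#' s <- data.frame(assay = c("RPF", "RNA"), condition = "D0", replicate = 1)
#' filter_detected(expr_set(m, s))   # g1 and g5
#' @export
filter_detected <- function(counts, min_reads = 10, conditions = NULL) {
  stopifnot(inherits(counts, "expr_set"))
  if (counts$unit != "counts") {
    stop("wrong-unit: filter_detected requires raw counts, got ", counts$unit,
         call. = FALSE)
  }
  conditions <- conditions %||% unique(counts$samples$condition)
  keep <- rep(TRUE, nrow(counts$mat))
  for (cond in conditions) {
    for (assay in c("RPF", "RNA")) {
      sel <- counts$samples$assay == assay & counts$samples$condition == cond
      if (!any(sel)) {
        stop("filter_detected: no ", assay, " libraries for condition ", cond,
             call. = FALSE)
      }
      pooled <- rowSums(counts$mat[, sel, drop = FALSE])
      keep <- keep & pooled >= min_reads
    }
  }
  rownames(counts$mat)[keep]
}

#' RPKM normalisation
#'
#' Reads per kilobase of coding sequence per million mapped reads:
#' `count / (cds_len/1000) / (column_total/1e6)`, where the column total is
#' the per-library sum of counts over the analysed genes. The CDS length is
#' used as the length denominator for both assays.
#'
#' @param counts An [expr_set()] of raw counts (typically already restricted
#'   to the detected gene list).
#' @param genes Annotation data frame with `gene_id` and `cds_len`.
#' @return An [expr_set()] with unit `"RPKM"`.
#' @export
rpkm <- function(counts, genes) {
  stopifnot(inherits(counts, "expr_set"))
  if (counts$unit != "counts") {
    stop("wrong-unit: rpkm requires raw counts", call. = FALSE)
  }
  len <- genes$cds_len[match(rownames(counts$mat), genes$gene_id)]
  if (anyNA(len)) stop("rpkm: genes missing from annotation", call. = FALSE)
  if (any(len <= 0)) stop("rpkm: cds_len must be > 0", call. = FALSE)
  totals <- colSums(counts$mat)
  if (any(totals <= 0)) {
    stop("degenerate-sample: zero column total in ",
         paste(colnames(counts$mat)[totals <= 0], collapse = ", "),
         call. = FALSE)
  }
  mat <- sweep(counts$mat / (len / 1000), 2, totals / 1e6, "/")
  expr_set(mat, counts$samples, unit = "RPKM")
}

#' Translational-efficiency matrix
#'
#' Translational efficiency (Eff) is the ribosome-footprint RPKM divided by
#' the RNA-seq RPKM, computed per (condition, replicate) pair. With a zero
#' pseudocount, entries with zero RNA signal are returned as `NA`
#' (undefined), never infinite.
#'
#' @param rpkm_es An [expr_set()] in RPKM containing both assays, or just
#'   the RPF assay if `rna` is supplied.
#' @param rna Optional separate RNA [expr_set()] (RPKM).
#' @param pseudocount Non-negative value added to both numerator and
#'   denominator (default 0).
#' @return A list of class `eff_matrix`: `mat` (gene x pair matrix, columns
#'   `<condition>_rep<k>`), `pairs` (data frame `condition`, `replicate`)
#'   and `pseudocount`.
#' @export
translational_efficiency <- function(rpkm_es, rna = NULL, pseudocount = 0) {
  stopifnot(inherits(rpkm_es, "expr_set"))
  if (pseudocount < 0) stop_invalid("pseudocount must be >= 0")
  if (is.null(rna)) {
    rpf <- subset_expr(rpkm_es, assay = "RPF")
    rna <- subset_expr(rpkm_es, assay = "RNA")
  } else {
    rpf <- subset_expr(rpkm_es, assay = "RPF")
    rna <- subset_expr(rna, assay = "RNA")
  }
  if (rpf$unit != "RPKM" || rna$unit != "RPKM") {
    stop("wrong-unit: translational_efficiency requires RPKM", call. = FALSE)
  }
  if (!identical(rownames(rpf$mat), rownames(rna$mat))) {
    stop("pairing error: RPF and RNA gene sets differ", call. = FALSE)
  }
  key <- function(s) paste(s$condition, s$replicate, sep = "::")
  if (!setequal(key(rpf$samples), key(rna$samples)) ||
      ncol(rpf$mat) != ncol(rna$mat)) {
    stop("pairing error: (condition, replicate) sets differ between assays",
         call. = FALSE)
  }
  ord <- match(key(rpf$samples), key(rna$samples))
  num <- rpf$mat + pseudocount
  den <- rna$mat[, ord, drop = FALSE] + pseudocount
  mat <- num / den
  mat[den == 0] <- NA_real_   # undefined, not infinite
  pairs <- rpf$samples[, c("condition", "replicate")]
  colnames(mat) <- paste0(pairs$condition, "_rep", pairs$replicate)
  structure(list(mat = mat, pairs = pairs, pseudocount = pseudocount),
            class = "eff_matrix")
}

#' Sample-sample correlation matrix
#'
#' Pearson correlation between libraries on `log2(x + 1)`-transformed
#' values. Pairs involving a constant column are undefined and returned as
#' `NA` (with a warning).
#'
#' @param es An [expr_set()] (counts or RPKM) with >= 2 samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  if (ncol(es$mat) < 2L) stop("sample_correlation: need >= 2 samples", call. = FALSE)
  lx <- log2(es$mat + 1)
  const <- apply(lx, 2, function(v) stats::sd(v) == 0)
  cc <- suppressWarnings(stats::cor(lx, method = "pearson"))
  if (any(const)) {
    warning("undefined-correlation: constant column(s) ",
            paste(colnames(lx)[const], collapse = ", "))
    cc[const, ] <- NA_real_
    cc[, const] <- NA_real_
  }
  diag(cc) <- 1
  cc
}

#' Average-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering on the distance `1 - correlation`, with a
#' deterministic tie-break: samples are ordered lexicographically by name
#' before clustering, so permuting the input order yields an isomorphic
#' tree.
#'
#' @param corr Sample correlation matrix from [sample_correlation()].
#' @return An object of class `hclust`.
#' @export
hierarchical_cluster <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop("hierarchical_cluster: need a square correlation matrix", call. = FALSE)
  }
  if (anyNA(corr)) {
    stop("hierarchical_cluster: correlation matrix contains NA", call. = FALSE)
  }
  ord <- order(rownames(corr))
  corr <- corr[ord, ord, drop = FALSE]
  if (nrow(corr) == 1L) {
    stop("hierarchical_cluster: single sample gives a trivial tree", call. = FALSE)
  }
  stats::hclust(stats::as.dist(1 - corr), method = "average")
}

#' Leaf labels of the two top-level branches of a dendrogram
#'
#' @param hc An `hclust` tree.
#' @return List of two character vectors (sample names per branch).
#' @export
top_bipartition <- function(hc) {
  ct <- stats::cutree(hc, k = 2)
  split(names(ct), ct)
}
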