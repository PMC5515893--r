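#' Gene-by-sample expression container
#'
#' A lightweight container tying a non-negative gene x sample matrix to its
#' sample metadata. Every column is one sequencing library, identified by its
#' assay (`RPF` for ribosome-protected fragments or `RNA` for RNA-seq), its
#' biological condition and its replicate number. The paired design requires
#' that every (condition, replicate) profiled by RPF is also profiled by RNA.
#'
#' @param mat Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns. All values must be non-negative.
#' @param samples Data frame with one row per column of `mat` and columns
#'   `assay` (`"RPF"` or `"RNA"`), `condition` (character label) and
#'   `replicate` (integer >= 1). Row order matches column order of `mat`.
#' @param unit `"counts"` (raw reads) or `"RPKM"`.
#' @return An object of class `expr_set`: a list with elements `mat`,
#'   `samples`, `unit`.
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), NULL))
#' s <- data.frame(assay = rep(c("RPF", "RNA"), each = 2),
#'                 condition = "D0", replicate = c(1, 2, 1, 2))
#' es <- expr_set(m, s)
#' dim(es$mat)
#' @export
expr_set <- function(mat, samples, unit = c("counts", "RPKM")) {
  unit <- match.arg(unit)
  mat <- as.matrix(mat)
  if (any(!is.finite(mat)) || any(mat < 0)) {
    stop("expr_set: matrix must be finite and non-negative", call. = FALSE)
  }
  if (is.null(rownames(mat))) {
    stop("expr_set: matrix must have gene ids as rownames", call. = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("assay", "condition", "replicate")
  if (!all(req %in% names(samples)) || nrow(samples) != ncol(mat)) {
    stop("expr_set: samples must describe every column (assay, condition, replicate)",
         call. = FALSE)
  }
  if (!all(samples$assay %in% c("RPF", "RNA"))) {
    stop("expr_set: assay must be 'RPF' or 'RNA'", call. = FALSE)
  }
  samples$replicate <- as.integer(samples$replicate)
  if (any(samples$replicate < 1L)) {
    stop("expr_set: replicate numbers start at 1", call. = FALSE)
  }
  # paired design: each RPF library must have its RNA partner
  key <- function(a) {
    sub <- samples[samples$assay == a, , drop = FALSE]
    paste(sub$condition, sub$replicate, sep = "::")
  }
  if (!all(key("RPF") %in% key("RNA"))) {
    stop("expr_set: unpaired design - every RPF (condition, replicate) needs an RNA partner",
         call. = FALSE)
  }
  colnames(mat) <- sample_names(samples)
  structure(list(mat = mat, samples = samples, unit = unit),
            class = "expr_set")
}

sample_names <- function(samples) {
  paste0(samples$assay, "_", samples$condition, "_rep", samples$replicate)
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples [%s]\n",
              nrow(x$mat), ncol(x$mat), x$unit))
  tab <- table(x$samples$assay, x$samples$condition)
  print(tab)
  invisible(x)
}

#' Subset an expression set
#'
#' @param es An `expr_set`.
#' @param genes Character vector of gene ids (kept in the given order), or
#'   `NULL` to keep all.
#' @param assay Optional assay to keep (`"RPF"` or `"RNA"`).
#' @param conditions Optional conditions to keep.
#' @return An `expr_set` restricted to the requested genes/samples.
#' @export
subset_expr <- function(es, genes = NULL, assay = NULL, conditions = NULL) {
  stopifnot(inherits(es, "expr_set"))
  mat <- es$mat
  samples <- es$samples
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(mat))
    if (length(missing)) {
      stop("subset_expr: unknown genes: ", paste(utils::head(missing), collapse = ", "),
           call. = FALSE)
    }
    mat <- mat[genes, , drop = FALSE]
  }
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(assay)) keep <- keep & samples$assay %in% assay
  if (!is.null(conditions)) keep <- keep & samples$condition %in% conditions
  out <- structure(list(mat = mat[, keep, drop = FALSE],
                        samples = samples[keep, , drop = FALSE],
                        unit = es$unit),
                   class = "expr_set")
  rownames(out$samples) <- NULL
  out
}

#' Write an expression set to TSV
#'
#' First column `gene_id`, then one column per library named
#' `<assay>_<condition>_rep<k>`.
#'
#' @param es An `expr_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expr_set <- function(es, path) {
  stopifnot(inherits(es, "expr_set"))
  df <- data.frame(gene_id = rownames(es$mat), es$mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an expression set from TSV
#'
#' Parses library names of the form `<assay>_<condition>_rep<k>` back into
#' sample metadata.
#'
#' @param path Path to a TSV written by [write_expr_set()].
#' @param unit `"counts"` or `"RPKM"`.
#' @return An `expr_set`.
#' @export
read_expr_set <- function(path, unit = c("counts", "RPKM")) {
  unit <- match.arg(unit)
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  nm <- colnames(mat)
  m <- regmatches(nm, regexec("^(RPF|RNA)_(.+)_rep([0-9]+)$", nm))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("read_expr_set: malformed sample name(s): ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  }
  samples <- data.frame(
    assay = vapply(m, `[`, "", 2L),
    condition = vapply(m, `[`, "", 3L),
    replicate = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  expr_set(mat, samples, unit = unit)
}
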