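# Shared in-code fixtures for the test suite.

# minimal paired expression set from a matrix of per-assay columns
make_es <- function(mat, assay, condition, replicate, unit = "counts") {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  expr_set(mat,
           data.frame(assay = assay, condition = condition,
                      replicate = replicate, stringsAsFactors = FALSE),
           unit = unit)
}

# tiny gene annotation with round numbers
tiny_genes <- function(n = 3, utr5 = 10, cds = 30, utr3 = 12) {
  data.frame(gene_id = paste0("g", seq_len(n)),
             utr5_len = utr5, cds_len = cds, utr3_len = utr3,
             categories = "", stringsAsFactors = FALSE)
}

# small but realistic simulation for recovery tests
small_sim_config <- function(n_genes = 1000, seed = 42, ...) {
  sim_config(n_genes = n_genes, n_families = 20, targets_per_family = 50,
             seed = seed, ...)
}
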