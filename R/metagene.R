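# Metagene analysis of positional footprint data. Coordinates are 0-based,
# transcript-relative throughout: position 0 is the transcript's first
# nucleotide, the start codon begins at utr5_len, the stop codon at
# utr5_len + cds_len - 3.

#' Shift 5'-end counts to P-site coordinates
#'
#' The ribosomal P-site of a footprint is located a fixed number of
#' nucleotides downstream of its 5' end (14 nt by default). Counts at 5'
#' position `p` are reassigned to `p + offset`; reads whose shifted position
#' falls beyond the transcript are dropped and counted.
#'
#' @param positions Numeric vector of per-position 5'-end counts (index `i`
#'   = transcript position `i - 1`).
#' @param offset Non-negative P-site offset in nt (default 14).
#' @return A list: `counts` (same-length vector in P-site coordinates) and
#'   `dropped` (number of reads lost off the 3' end).
#' @examples
#' v <- integer(60); v[37] <- 1          # one read with 5' end at position 36
#' psite_shift(v)$counts[51] == 1        # P-site at position 50
#' @export
psite_shift <- function(positions, offset = 14L) {
  if (offset < 0) stop_invalid("P-site offset must be >= 0")
  offset <- as.integer(offset)
  n <- length(positions)
  out <- numeric(n)
  if (offset == 0L) {
    return(list(counts = positions, dropped = 0))
  }
  keep <- seq_len(n - offset)
  out[keep + offset] <- positions[keep]
  dropped <- sum(positions[seq.int(n - offset + 1L, n)])
  list(counts = out, dropped = dropped)
}

# window positions of a gene's anchored vector; returns values (normalized)
# aligned to window offsets, NA outside the transcript
window_values <- function(vec, anchor, window) {
  idx <- anchor + window + 1L            # 1-based index into vec
  ok <- idx >= 1L & idx <= length(vec)
  out <- rep(NA_real_, length(window))
  out[ok] <- vec[idx[ok]]
  out
}

#' Metagene footprint-density profile
#'
#' Averages per-gene footprint density over a window anchored at the first
#' nucleotide of the start codon or of the stop codon. Each gene's windowed
#' vector is first divided by that gene's mean CDS density, so a uniformly
#' covered CDS contributes a flat profile at 1; genes with zero CDS density
#' are skipped, and positions outside a short transcript contribute nothing
#' (per-position gene tallies are tracked).
#'
#' @param psites Named list of P-site count vectors (one per gene, full
#'   transcript length), e.g. from [psite_shift()].
#' @param genes Annotation data frame (`gene_id`, `utr5_len`, `cds_len`,
#'   `utr3_len`).
#' @param align_at `"start"` or `"stop"`.
#' @param window Integer offsets relative to the anchor; defaults to
#'   -50..+100 for start and -100..+50 for stop.
#' @return A data frame of class `metagene_profile`: `offset`,
#'   `mean_density`, `n_genes` (genes contributing at that offset), with the
#'   total genes used in attribute `n_genes_used`.
#' @export
metagene_profile <- function(psites, genes, align_at = c("start", "stop"),
                             window = NULL) {
  align_at <- match.arg(align_at)
  if (!length(psites)) stop("empty-profile: no positional data", call. = FALSE)
  if (is.null(window)) {
    window <- if (align_at == "start") -50:100 else -100:50
  }
  window <- as.integer(window)
  acc <- numeric(length(window))
  tally <- integer(length(window))
  used <- 0L
  for (gid in names(psites)) {
    g <- genes[genes$gene_id == gid, ]
    if (!nrow(g)) next
    vec <- psites[[gid]]
    cds_idx <- seq.int(g$utr5_len + 1L, g$utr5_len + g$cds_len)
    mean_cds <- mean(vec[cds_idx])
    if (mean_cds == 0) next                 # undetectable gene, skipped
    anchor <- if (align_at == "start") g$utr5_len else g$utr5_len + g$cds_len - 3L
    w <- window_values(vec / mean_cds, anchor, window)
    ok <- !is.na(w)
    acc[ok] <- acc[ok] + w[ok]
    tally <- tally + ok
    used <- used + 1L
  }
  if (used == 0L) stop("empty-profile: no gene with non-zero CDS density", call. = FALSE)
  prof <- data.frame(offset = window,
                     mean_density = ifelse(tally > 0, acc / pmax(tally, 1L), NA_real_),
                     n_genes = tally)
  attr(prof, "align_at") <- align_at
  attr(prof, "n_genes_used") <- used
  class(prof) <- c("metagene_profile", "data.frame")
  prof
}

#' Codon-frame periodicity of P-sites
#'
#' Genuine translation leaves a 3-nucleotide periodicity: P-sites pile up in
#' one codon frame. This computes the fraction of in-CDS P-sites per frame
#' (`frame = (position - cds_start) mod 3`), a periodicity score
#' `max(fraction) - 1/3` (0 for uniform, 2/3 for perfectly framed), and a
#' chi-square test against the uniform frame distribution.
#'
#' @param psites Named list of P-site count vectors.
#' @param genes Annotation data frame.
#' @return A list: `fractions` (length 3), `score`, `chisq_stat`,
#'   `chisq_p`, `n_psites`. With zero in-CDS P-sites, `score` is `NA` and
#'   `undefined` is `TRUE`.
#' @export
periodicity_score <- function(psites, genes) {
  frame_counts <- numeric(3)
  for (gid in names(psites)) {
    g <- genes[genes$gene_id == gid, ]
    if (!nrow(g)) next
    vec <- psites[[gid]]
    cds_idx <- seq.int(g$utr5_len + 1L, g$utr5_len + g$cds_len)
    v <- vec[cds_idx]
    fr <- (cds_idx - (g$utr5_len + 1L)) %% 3L
    frame_counts <- frame_counts + vapply(0:2, function(f) sum(v[fr == f]), 0)
  }
  n <- sum(frame_counts)
  if (n == 0) {
    return(list(fractions = rep(NA_real_, 3), score = NA_real_,
                chisq_stat = NA_real_, chisq_p = NA_real_,
                n_psites = 0, undefined = TRUE))
  }
  fr <- frame_counts / n
  ch <- suppressWarnings(stats::chisq.test(frame_counts, p = rep(1 / 3, 3)))
  list(fractions = fr, score = max(fr) - 1 / 3,
       chisq_stat = unname(ch$statistic), chisq_p = ch$p.value,
       n_psites = n, undefined = FALSE)
}

#' Convert a long positional table to per-gene vectors
#'
#' @param df Data frame `gene_id`, `position` (0-based), `count`.
#' @param genes Annotation data frame (for transcript lengths).
#' @return Named list of full-length count vectors.
#' @export
positions_to_vectors <- function(df, genes) {
  lens <- stats::setNames(genes$utr5_len + genes$cds_len + genes$utr3_len,
                          genes$gene_id)
  out <- list()
  for (gid in unique(df$gene_id)) {
    if (!gid %in% names(lens)) {
      stop("positions_to_vectors: gene ", gid, " missing from annotation",
           call. = FALSE)
    }
    sub <- df[df$gene_id == gid, ]
    if (any(sub$position < 0 | sub$position >= lens[[gid]])) {
      stop("positions_to_vectors: position out of transcript bounds for ", gid,
           call. = FALSE)
    }
    v <- numeric(lens[[gid]])
    v[sub$position + 1L] <- sub$count
    out[[gid]] <- v
  }
  out
}
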