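# Cumulative-distribution comparison machinery: empirical CDFs, two-sample
# Kolmogorov-Smirnov tests (asymptotic, exact by enumeration for small
# samples, or permutation), gene-set shift tests against a background,
# ranked-list permutation enrichment, and hypergeometric category
# enrichment.

#' Empirical cumulative distribution function points
#'
#' @param values Numeric vector (n >= 1, finite).
#' @return A list: `support` (sorted unique values) and `cumfrac`
#'   (right-continuous cumulative fractions, reaching 1 at the maximum).
#' @export
ecdf_points <- function(values) {
  if (!length(values)) stop("ecdf: empty input", call. = FALSE)
  if (any(!is.finite(values))) stop("ecdf: non-finite values", call. = FALSE)
  support <- sort(unique(values))
  list(support = support,
       cumfrac = stats::ecdf(values)(support))
}

# two-sample KS statistic D = sup |F_x - F_y| over the pooled support
ks_statistic <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(pooled) - stats::ecdf(y)(pooled)))
}

# survival function of the Kolmogorov distribution:
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-8) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the two-sided KS statistic `D` over the pooled support and a
#' p-value by one of three routes: `asymptotic` (Kolmogorov distribution
#' with effective size `n_x n_y / (n_x + n_y)`), `exact_small` (complete
#' enumeration of all `choose(n_x + n_y, n_x)` label assignments; only for
#' `n_x + n_y <= 12`), or `permutation` (seeded label resampling).
#'
#' @param x,y Numeric vectors (finite, n >= 1 each).
#' @param mode `"asymptotic"`, `"exact_small"` or `"permutation"`.
#' @param n_permutations Permutations for `mode = "permutation"`
#'   (default 2000).
#' @param seed Seed for the permutation mode.
#' @return A list of class `ks_result`: `d_statistic`, `p_value`, `n_x`,
#'   `n_y`, `shift_direction` (`"right"` if `mean(x) > mean(y)`, `"left"`
#'   if smaller, `"none"` if equal or `D = 0`), `mode`.
#' @export
ks_two_sample <- function(x, y,
                          mode = c("asymptotic", "exact_small", "permutation"),
                          n_permutations = 2000, seed = 1L) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("ks_two_sample: empty sample", call. = FALSE)
  if (any(!is.finite(c(x, y)))) stop("ks_two_sample: non-finite values", call. = FALSE)
  d <- ks_statistic(x, y)
  nx <- length(x)
  ny <- length(y)
  eps <- 1e-12
  p <- switch(mode,
    asymptotic = {
      ne <- nx * ny / (nx + ny)
      kolmogorov_sf(sqrt(ne) * d)
    },
    exact_small = {
      if (nx + ny > 12L) {
        stop("ks_two_sample: exact_small limited to n_x + n_y <= 12", call. = FALSE)
      }
      pooled <- c(x, y)
      idx <- utils::combn(nx + ny, nx)
      hits <- 0L
      for (j in seq_len(ncol(idx))) {
        dj <- ks_statistic(pooled[idx[, j]], pooled[-idx[, j]])
        if (dj >= d - eps) hits <- hits + 1L
      }
      hits / ncol(idx)
    },
    permutation = {
      pooled <- c(x, y)
      with_seed(seed, {
        hits <- 0L
        for (j in seq_len(n_permutations)) {
          pick <- sample.int(nx + ny, nx)
          if (ks_statistic(pooled[pick], pooled[-pick]) >= d - eps) hits <- hits + 1L
        }
        (hits + 1) / (n_permutations + 1)
      })
    })
  dir <- if (d < eps || isTRUE(all.equal(mean(x), mean(y)))) {
    "none"
  } else if (mean(x) > mean(y)) "right" else "left"
  structure(list(d_statistic = d, p_value = p, n_x = nx, n_y = ny,
                 shift_direction = dir, mode = mode),
            class = "ks_result")
}

#' Gene-set shift test against a background
#'
#' Compares the cumulative distribution of a value (expression or fold
#' change) over a gene set with the background by the two-sample KS test.
#' `background_mode = "all_other_genes"` (default) uses the complement of
#' the set, keeping the two samples disjoint; `"all_genes"` compares the
#' set against all analysed genes including the set itself, the convention
#' of set-vs-total cumulative-fraction plots.
#'
#' @param values Named numeric vector (gene -> value).
#' @param gene_set Character vector of gene ids.
#' @param background_mode `"all_other_genes"` or `"all_genes"`.
#' @param mode KS p-value mode (see [ks_two_sample()]).
#' @param ... Passed to [ks_two_sample()].
#' @return A `ks_result` with an extra element `n_set_used`.
#' @export
set_shift_test <- function(values, gene_set,
                           background_mode = c("all_other_genes", "all_genes"),
                           mode = "asymptotic", ...) {
  background_mode <- match.arg(background_mode)
  if (is.null(names(values))) stop("set_shift_test: values must be named", call. = FALSE)
  inset <- names(values) %in% gene_set
  if (!any(inset)) stop("set_shift_test: gene set does not intersect the analysed genes",
                        call. = FALSE)
  x <- values[inset]
  y <- if (background_mode == "all_other_genes") values[!inset] else values
  if (!length(y)) stop("set_shift_test: empty background", call. = FALSE)
  res <- ks_two_sample(unname(x), unname(y), mode = mode, ...)
  res$n_set_used <- sum(inset)
  res$background_mode <- background_mode
  res
}

#' Ranked-list permutation enrichment
#'
#' Classic (unweighted) KS running-sum enrichment of a gene set in a ranked
#' gene list: walking down the ranking, the running sum gains
#' `1/n_set` at set members and loses `1/(n - n_set)` elsewhere; the
#' enrichment score ES is the extremum of the running sum. The normalised
#' enrichment score is `ES / mean(|ES|)` over gene-label permutations, and
#' the p-value is the fraction of permuted `|ES| >= |observed|`
#' (with a +1 continuity correction, so `p >= 1/(n_permutations + 1)`).
#'
#' @param ranking Data frame from [delta_eff_ranking()] (or any data frame
#'   with a `gene_id` column in ranked order), or a character vector of
#'   ranked gene ids.
#' @param gene_set Character vector of gene ids.
#' @param n_permutations Number of label permutations (default 1000; below
#'   100 a warning flag is set).
#' @param seed Integer seed.
#' @return A list of class `enrichment_result`: `es`, `nes`, `p_value`,
#'   `n_permutations`, `seed`, `n_set_used`, `low_permutations` flag.
#' @export
ranked_enrichment <- function(ranking, gene_set, n_permutations = 1000,
                              seed = 1L) {
  ids <- if (is.data.frame(ranking)) ranking$gene_id else as.character(ranking)
  n <- length(ids)
  hit <- ids %in% gene_set
  k <- sum(hit)
  if (k == 0L || k == n) {
    stop("ranked_enrichment: gene set must be a non-trivial subset of the ranking",
         call. = FALSE)
  }
  low <- n_permutations < 100
  if (low) warning("ranked_enrichment: fewer than 100 permutations")
  es_of <- function(hit) {
    step <- ifelse(hit, 1 / sum(hit), -1 / (length(hit) - sum(hit)))
    rs <- cumsum(step)
    rs[which.max(abs(rs))]
  }
  es <- es_of(hit)
  with_seed(seed, {
    perm <- vapply(seq_len(n_permutations), function(i) {
      es_of(hit[sample.int(n)])
    }, 0)
    nes <- es / mean(abs(perm))
    p <- (sum(abs(perm) >= abs(es)) + 1) / (n_permutations + 1)
    structure(list(es = es, nes = nes, p_value = p,
                   n_permutations = n_permutations, seed = seed,
                   n_set_used = k, low_permutations = low),
              class = "enrichment_result")
  })
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of observing at least the given overlap between a gene set
#' and a category when drawing the set uniformly from the universe.
#'
#' @param set_genes Character vector (the selected genes).
#' @param category_genes Character vector (the category).
#' @param universe Either the universe size (integer) or a character vector
#'   of universe gene ids. Set and category must lie inside the universe.
#' @return The upper-tail p-value `P(overlap >= observed)`.
#' @examples
#' hypergeometric_test(letters[1:5], letters[1:5], 10)  # 1/choose(10,5)
#' @export
hypergeometric_test <- function(set_genes, category_genes, universe) {
  set_genes <- unique(set_genes)
  category_genes <- unique(category_genes)
  if (is.character(universe)) {
    universe_ids <- unique(universe)
    if (!all(set_genes %in% universe_ids) || !all(category_genes %in% universe_ids)) {
      stop("hypergeometric_test: set and category must be inside the universe",
           call. = FALSE)
    }
    n_univ <- length(universe_ids)
  } else {
    n_univ <- as.integer(universe)
  }
  k <- length(set_genes)
  m <- length(category_genes)
  if (k > n_univ || m > n_univ) {
    stop("hypergeometric_test: inconsistent sizes", call. = FALSE)
  }
  q <- length(intersect(set_genes, category_genes))
  stats::phyper(q - 1, m, n_univ - m, k, lower.tail = FALSE)
}

#' KS shift tests for many gene sets
#'
#' Applies [set_shift_test()] to every set in a list and reports raw and
#' Benjamini-Hochberg-adjusted p-values.
#'
#' @param values Named numeric vector.
#' @param sets Named list of gene-id vectors.
#' @param ... Passed to [set_shift_test()].
#' @return Data frame: `set`, `n_set`, `d_statistic`, `shift_direction`,
#'   `p_value`, `fdr`.
#' @export
set_shift_table <- function(values, sets, ...) {
  rows <- lapply(names(sets), function(nm) {
    r <- set_shift_test(values, sets[[nm]], ...)
    data.frame(set = nm, n_set = r$n_set_used, d_statistic = r$d_statistic,
               shift_direction = r$shift_direction, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}
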