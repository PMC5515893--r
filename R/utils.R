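# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with `set.seed(seed)` while preserving (and afterwards
#' restoring) the caller's `.Random.seed`, so that seeded generator calls do
#' not perturb the global RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("invalid-config: 'seed' must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed
#'
#' Maps a base seed and a stage label to a deterministic child seed below
#' 2^31, so independent stages of an analysis draw from unrelated but fully
#' reproducible RNG streams.
#'
#' @param seed Integer base seed.
#' @param label Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1000003 + h) %% .Machine$integer.max)
}

stop_invalid <- function(...) {
  stop("invalid-config: ", ..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round to nearest multiple of 3, never below 3
round_to_codon <- function(x) {
  pmax(3L, as.integer(round(x / 3) * 3))
}

#' Write a data frame as TSV
#'
#' Plain tab-separated output with a header and no quoting, the on-disk
#' format used for all tabular artifacts of the pipeline.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
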