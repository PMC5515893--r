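# End-to-end orchestration: simulate (or ingest) -> filter/quantify ->
# metagene -> driver classification per contrast -> category set-shift ->
# microRNA analysis, with a manifest recording every artifact, the config
# hash and the seed so identical inputs give byte-identical outputs.

#' Pipeline run configuration
#'
#' @param sim A [sim_config()] describing the synthetic experiment, or
#'   `NULL` when counts/annotation are supplied as files.
#' @param counts_file,annotation_file,targets_file Input TSVs (used when
#'   `sim` is `NULL`): counts as written by [write_expr_set()], annotation
#'   and target tables as written by [simulate_experiment()].
#' @param contrasts Named list of `c(a = <reference>, b = <treatment>)`
#'   condition pairs.
#' @param rpf_fold Named numeric vector: RPF fold-change threshold per
#'   contrast (default 4 for the differentiation contrasts and 2 for the
#'   tissue contrast).
#' @param min_reads Detection filter threshold (default 10).
#' @param fc_pseudocount Pseudocount for fold changes (default 0.5).
#' @param fc_normalize Fold-change normalization mode passed to
#'   [fold_changes()] (default `"median"`: per-assay median centring, which
#'   removes the library-composition shift RPKM fold changes carry when
#'   many genes change in one direction).
#' @param mirna_tissues Length-2 character vector: the two conditions
#'   compared in the microRNA cross-tissue analysis (default BAT, WAT);
#'   `NULL` disables the microRNA stage.
#' @param n_footprint_genes Genes for the metagene stage when simulating
#'   (default 50; 0 disables).
#' @param outdir Output directory.
#' @param seed Integer seed for every stochastic stage.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       counts_file = NULL, annotation_file = NULL,
                       targets_file = NULL,
                       contrasts = list(brown = c(a = "BATD0", b = "BATD5"),
                                        white = c(a = "WATD0", b = "WATD5"),
                                        tissue = c(a = "WAT", b = "BAT")),
                       rpf_fold = c(brown = 4, white = 4, tissue = 2),
                       min_reads = 10,
                       fc_pseudocount = 0.5,
                       fc_normalize = c("median", "none"),
                       mirna_tissues = c("BAT", "WAT"),
                       n_footprint_genes = 50,
                       outdir = tempfile("ribotrans_run_"),
                       seed = 1L) {
  if (is.null(sim) && (is.null(counts_file) || is.null(annotation_file))) {
    stop_invalid("either a simulation config or counts/annotation files are required")
  }
  if (any(rpf_fold <= 1)) stop_invalid("rpf_fold thresholds must be > 1")
  if (min_reads < 0) stop_invalid("min_reads must be >= 0")
  if (!all(names(contrasts) %in% names(rpf_fold))) {
    stop_invalid("every contrast needs an rpf_fold threshold")
  }
  fc_normalize <- match.arg(fc_normalize)
  structure(list(sim = sim, counts_file = counts_file,
                 annotation_file = annotation_file, targets_file = targets_file,
                 contrasts = contrasts, rpf_fold = rpf_fold,
                 min_reads = min_reads, fc_pseudocount = fc_pseudocount,
                 fc_normalize = fc_normalize,
                 mirna_tissues = mirna_tissues,
                 n_footprint_genes = n_footprint_genes,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; the `sim`
#' block, if present, onto [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) sim <- do.call(sim_config, y$sim)
  args <- y[setdiff(names(y), "sim")]
  if (!is.null(args$contrasts)) {
    args$contrasts <- lapply(args$contrasts, function(p) c(a = p$a, b = p$b))
  }
  if (!is.null(args$rpf_fold)) args$rpf_fold <- unlist(args$rpf_fold)
  do.call(run_config, c(list(sim = sim), args))
}

config_hash <- function(config) {
  # the hash covers the analysis settings, not where outputs land
  cfg <- unclass(config)
  cfg$outdir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data generation or ingestion, detection filtering,
#' RPKM and translational-efficiency quantification, sample correlation and
#' clustering, metagene profiling (simulated footprints), per-contrast fold
#' changes and driver classification, annotation-category set-shift tests
#' on each contrast's Eff fold changes, and the microRNA target-repression
#' analysis. Every artifact is a TSV or JSON file under `config$outdir` and
#' is listed in the returned manifest together with its producing stage.
#'
#' @param config A [run_config()].
#' @return The manifest (list with `config_hash`, `seed`, `n_genes_analysed`,
#'   `files`, `stages`, `summary`), invisibly also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  files <- character(0)
  stages <- character(0)
  # manifest records paths relative to outdir so reruns in different
  # directories remain byte-identical
  add_file <- function(name, rel_path, stage) {
    files[[name]] <<- rel_path
    stages[[name]] <<- stage
  }

  # -- stage: data ----------------------------------------------------------
  pipeline_log("stage data: %s",
               if (is.null(config$sim)) "ingesting files" else "simulating")
  if (is.null(config$sim)) {
    counts <- read_expr_set(config$counts_file, unit = "counts")
    genes <- read_tsv(config$annotation_file)
    if (is.null(genes$categories)) genes$categories <- ""
    genes$categories <- as.character(genes$categories)
    genes$categories[is.na(genes$categories)] <- ""
    targets <- if (!is.null(config$targets_file)) read_tsv(config$targets_file)
               else NULL
    truth <- NULL
    fp <- NULL
  } else {
    sim <- config$sim
    sim$seed <- config$seed
    exp <- simulate_experiment(sim, outdir = p("sim"),
                               n_footprint_genes = config$n_footprint_genes)
    counts <- exp$counts
    genes <- exp$ann$genes
    targets <- exp$ann$targets
    truth <- exp$truth
    fp <- exp$footprints
    for (nm in names(exp$files)) {
      add_file(paste0("sim_", nm), file.path("sim", basename(exp$files[[nm]])),
               "data")
    }
  }
  used_conditions <- unique(unlist(config$contrasts, use.names = FALSE))
  missing_cond <- setdiff(used_conditions, unique(counts$samples$condition))
  if (length(missing_cond)) {
    stop_invalid("contrast condition(s) absent from the data: ",
                 paste(missing_cond, collapse = ", "))
  }

  # -- stage: quantify ------------------------------------------------------
  pipeline_log("stage quantify")
  detected <- filter_detected(counts, min_reads = config$min_reads)
  counts_f <- subset_expr(counts, genes = detected)
  rp <- rpkm(counts_f, genes)
  eff <- translational_efficiency(rp)
  corr <- sample_correlation(rp)
  hc <- hierarchical_cluster(corr)
  write_expr_set(rp, p("rpkm.tsv"))
  write_tsv(data.frame(gene_id = rownames(eff$mat), eff$mat,
                       check.names = FALSE), p("eff.tsv"))
  write_tsv(data.frame(sample = rownames(corr), corr, check.names = FALSE),
            p("sample_correlation.tsv"))
  jsonlite::write_json(list(labels = hc$labels, merge = hc$merge,
                            height = hc$height),
                       p("clustering.json"), auto_unbox = TRUE, digits = NA)
  add_file("rpkm", "rpkm.tsv", "quantify")
  add_file("eff", "eff.tsv", "quantify")
  add_file("sample_correlation", "sample_correlation.tsv", "quantify")
  add_file("clustering", "clustering.json", "quantify")

  # -- stage: metagene ------------------------------------------------------
  metagene_summary <- NULL
  if (!is.null(fp) && nrow(fp)) {
    pipeline_log("stage metagene (%d genes)", length(unique(fp$gene_id)))
    vecs <- positions_to_vectors(fp, genes)
    psv <- lapply(vecs, function(v) psite_shift(v)$counts)
    prof <- metagene_profile(psv, genes, align_at = "start")
    peri <- periodicity_score(psv, genes)
    write_tsv(prof, p("metagene_start.tsv"))
    add_file("metagene_start", "metagene_start.tsv", "metagene")
    metagene_summary <- list(peak_offset = prof$offset[which.max(prof$mean_density)],
                             frame_fractions = peri$fractions,
                             periodicity_score = peri$score)
  }

  # -- stage: classify ------------------------------------------------------
  pipeline_log("stage classify (%d contrasts)", length(config$contrasts))
  fc_tables <- list()
  driver_summaries <- list()
  for (cn in names(config$contrasts)) {
    ctr <- config$contrasts[[cn]]
    fc <- fold_changes(rp, ctr[["a"]], ctr[["b"]],
                       pseudocount = config$fc_pseudocount,
                       normalize = config$fc_normalize)
    fc_tables[[cn]] <- fc
    asg <- classify_drivers(fc, rpf_fold_threshold = config$rpf_fold[[cn]])
    fc_out <- fc
    fc_out$group <- asg$group[match(fc$gene_id, asg$gene_id)]
    fc_out$category <- asg$category[match(fc$gene_id, asg$gene_id)]
    write_tsv(fc_out, p(sprintf("assignments_%s.tsv", cn)))
    add_file(paste0("assignments_", cn), sprintf("assignments_%s.tsv", cn),
             "classify")
    s <- summarize_driver_classes(asg)
    # named lists survive JSON serialisation with their names intact
    s$counts <- as.list(s$counts)
    s$percent <- as.list(s$percent)
    driver_summaries[[cn]] <- s
  }

  # -- stage: setshift ------------------------------------------------------
  shift_summaries <- list()
  cat_sets <- category_sets(genes)
  cat_sets <- cat_sets[vapply(cat_sets, length, 1L) > 0]
  if (length(cat_sets)) {
    pipeline_log("stage setshift (%d categories)", length(cat_sets))
    for (cn in names(fc_tables)) {
      fc <- fc_tables[[cn]]
      vals <- stats::setNames(fc$log2_eff_fc, fc$gene_id)
      tab <- set_shift_table(vals, cat_sets)
      write_tsv(tab, p(sprintf("shifts_%s.tsv", cn)))
      add_file(paste0("shifts_", cn), sprintf("shifts_%s.tsv", cn), "setshift")
      shift_summaries[[cn]] <- tab
    }
  }

  # -- stage: mirna ---------------------------------------------------------
  mirna_summary <- NULL
  if (!is.null(targets) && nrow(targets) && !is.null(config$mirna_tissues)) {
    tis <- config$mirna_tissues
    if (all(tis %in% counts$samples$condition)) {
      pipeline_log("stage mirna (%d target rows)", nrow(targets))
      fams <- collapse_families(targets)
      recs <- list()
      for (tt in tis) {
        sel <- rp$samples$assay == "RNA" & rp$samples$condition == tt
        vals <- rowMeans(rp$mat[, sel, drop = FALSE])
        recs[[tt]] <- family_repression_table(vals, fams, metric = "RNA",
                                              tissue = tt)
      }
      all_recs <- do.call(rbind, recs)
      write_tsv(all_recs, p("mirna_results.tsv"))
      add_file("mirna_results", "mirna_results.tsv", "mirna")
      frac <- stronger_repression_fraction(recs[[tis[1]]], recs[[tis[2]]])
      mirna_summary <- list(
        n_families = length(unique(fams$family_id)),
        n_repressed = stats::setNames(
          lapply(tis, function(tt) sum(recs[[tt]]$repressed, na.rm = TRUE)), tis),
        stronger_in = tis[1],
        stronger_fraction = frac$fraction,
        n_eligible = frac$n_eligible
      )
    }
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_genes_analysed = length(detected),
    files = as.list(files),
    stages = as.list(stages),
    summary = list(drivers = driver_summaries,
                   metagene = metagene_summary,
                   shifts = lapply(shift_summaries, function(t) {
                     stats::setNames(as.list(t$p_value), t$set)
                   }),
                   mirna = mirna_summary)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  pipeline_log("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  manifest
}

#' Human-readable report from a pipeline manifest
#'
#' @param manifest Manifest list from [run_pipeline()] or the path to a
#'   `manifest.json`.
#' @return Character vector of markdown lines (also printable with `cat`).
#' @export
report <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  lines <- c("# Translatome analysis report", "",
             sprintf("- config hash: %s", manifest$config_hash),
             sprintf("- seed: %s", manifest$seed),
             sprintf("- genes analysed: %s", manifest$n_genes_analysed), "")
  drv <- manifest$summary$drivers
  if (length(drv)) {
    for (cn in names(drv)) {
      s <- drv[[cn]]
      lines <- c(lines, sprintf("## Driver classes: %s", cn), "")
      if (isTRUE(s$empty) || (!is.null(s$total) && s$total == 0)) {
        lines <- c(lines, "no genes passed threshold", "")
      } else {
        cats <- names(s$counts)
        for (i in seq_along(cats)) {
          lines <- c(lines, sprintf("- %s: %s (%.1f%%)", cats[i],
                                    s$counts[[i]], as.numeric(s$percent[[i]])))
        }
        lines <- c(lines, sprintf("- total classified: %s", s$total), "")
      }
    }
  } else {
    warning("partial-report: no driver summaries in manifest")
  }
  sh <- manifest$summary$shifts
  if (length(sh)) {
    lines <- c(lines, "## Gene-set shift tests (Eff fold change)", "")
    for (cn in names(sh)) {
      for (set in names(sh[[cn]])) {
        lines <- c(lines, sprintf("- %s / %s: KS p = %.3g", cn, set,
                                  as.numeric(sh[[cn]][[set]])))
      }
    }
    lines <- c(lines, "")
  }
  mg <- manifest$summary$metagene
  if (!is.null(mg)) {
    lines <- c(lines, "## Metagene", "",
               sprintf("- start-aligned profile peak at offset %s", mg$peak_offset),
               sprintf("- periodicity score: %.3f", as.numeric(mg$periodicity_score)),
               "")
  }
  mi <- manifest$summary$mirna
  if (!is.null(mi)) {
    lines <- c(lines, "## microRNA target repression", "",
               sprintf("- families analysed: %s", mi$n_families),
               sprintf("- fraction repressing more strongly in %s: %.3f (n = %s eligible)",
                       mi$stronger_in, as.numeric(mi$stronger_fraction),
                       mi$n_eligible),
               "")
  }
  lines
}
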