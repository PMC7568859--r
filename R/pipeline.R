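# Run configuration and the end-to-end pipeline driver:
# stats -> extract -> fit -> signal -> topology tests, with a manifest.

validation_error <- function(...) {
  stop(structure(class = c("validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Run configuration for the conflict-dissection pipeline
#'
#' Validates and freezes everything a pipeline run depends on. Either a
#' synthetic preset (`preset = "laureae-like"`) or real inputs (alignment +
#' partition + candidate topology files) must be given.
#'
#' @param preset `NULL` or `"laureae-like"` (simulate the preset
#'   planted-conflict dataset).
#' @param alignment,partition paths to a FASTA alignment and a RAxML-style
#'   partition file (required when `preset` is `NULL`).
#' @param topologies named character vector of Newick files with the
#'   candidate topologies (ignored with a preset, which supplies T1-T3).
#' @param mask_threshold optional gap-fraction threshold for column masking.
#' @param strong,moderate delta-lnL classification thresholds.
#' @param n_rell RELL replicates for the topology tests.
#' @param seed integer seed (mandatory).
#' @param fit_model optimise model parameters during fitting (branch
#'   lengths are always optimised).
#' @param n_loci,n_conflict preset dataset geometry.
#' @param length_range preset locus-length range (bp).
#' @return validated list of class `"run_config"`.
#' @export
run_config <- function(preset = NULL, alignment = NULL, partition = NULL,
                       topologies = NULL, mask_threshold = NULL,
                       strong = 2.0, moderate = 1.0, n_rell = 10000L,
                       seed = NULL, fit_model = FALSE, n_loci = 243L,
                       n_conflict = 6L, length_range = c(100L, 3000L)) {
  if (is.null(seed)) validation_error("a seed is required")
  if (!(strong > moderate && moderate > 0))
    validation_error("thresholds must satisfy strong > moderate > 0")
  if (is.null(preset)) {
    for (p in c(alignment, partition, unname(topologies)))
      if (!file.exists(p)) validation_error("input file not found: ", p)
    if (is.null(alignment) || is.null(partition) || length(topologies) < 2L)
      validation_error("need alignment, partition and >= 2 topology files")
    if (is.null(names(topologies)))
      names(topologies) <- paste0("T", seq_along(topologies))
  } else if (!identical(preset, "laureae-like"))
    validation_error("unknown preset: ", preset)
  structure(list(preset = preset, alignment = alignment, partition = partition,
                 topologies = topologies, mask_threshold = mask_threshold,
                 strong = strong, moderate = moderate,
                 n_rell = as.integer(n_rell), seed = as.integer(seed),
                 fit_model = isTRUE(fit_model), n_loci = as.integer(n_loci),
                 n_conflict = as.integer(n_conflict),
                 length_range = as.integer(length_range)),
            class = "run_config")
}

#' Read a run configuration from a plain-text `key = value` file
#'
#' Recognised keys mirror the arguments of [run_config()]; `topologies`
#' takes comma-separated `name:path` entries.
#'
#' @param path config file.
#' @param ... overrides applied on top of the file (CLI precedence).
#' @return a [run_config()].
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) validation_error("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- list()
  for (p in kv) {
    key <- p[1]; val <- paste(p[-1], collapse = "=")
    args[[key]] <- switch(key,
      seed = , n_rell = , n_loci = , n_conflict = as.integer(val),
      strong = , moderate = , mask_threshold = as.numeric(val),
      fit_model = as.logical(val),
      length_range = as.integer(strsplit(val, ",")[[1]]),
      topologies = {
        parts <- strsplit(strsplit(val, ",")[[1]], ":")
        stats::setNames(vapply(parts, `[`, "", 2L),
                        vapply(parts, `[`, "", 1L))
      },
      val)
  }
  args <- utils::modifyList(args, list(...))
  do.call(run_config, args)
}

stage_log <- function(log, stage, t0, ...) {
  entry <- list(stage = stage, wall_s = round(as.numeric(Sys.time()) - t0, 3), ...)
  c(log, list(entry))
}

#' Run the full conflict-dissection pipeline
#'
#' Executes dataset acquisition (simulation or file input), optional gap
#' masking, per-topology fixed-topology fitting, locus-wise delta-lnL
#' dissection, and the RELL topology tests, writing each stage's outputs
#' (FASTA, partition, TSV tables, Newick trees) to `out_dir` before the
#' next stage starts, plus a machine-readable JSON manifest (input hashes,
#' seed, package version, per-stage wall time). Identical config and inputs
#' give identical outputs. On stage failure a `FAILED` marker naming the
#' stage is left in `out_dir` and the error is re-raised.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created; must be empty or absent unless
#'   `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return (invisibly) list with the main in-memory results: `alignment`,
#'   `partition`, `lnl_matrix`, `dissection`, `tests`, `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir, overwrite = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    validation_error("output directory not empty: ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(e)
  }
  tryCatch({
    t0 <- as.numeric(Sys.time()); stage <- "dataset"
    if (!is.null(cfg$preset)) {
      sim <- simulate_conflict_dataset(conflict_sim_config(
        n_loci = cfg$n_loci, n_conflict = cfg$n_conflict,
        length_range = cfg$length_range, seed = cfg$seed))
      aln <- sim$alignment; part <- sim$partition
      topologies <- list(T1 = preset_topology("T1"),
                         T2 = preset_topology("T2"),
                         T3 = preset_topology("T3"))
      model <- preset_model()
      utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      aln <- read_fasta_alignment(cfg$alignment)
      part <- read_partition_file(cfg$partition)
      topologies <- lapply(cfg$topologies, ape::read.tree)
      model <- preset_model()
    }
    write_fasta_alignment(aln, file.path(out_dir, "alignment.fasta"))
    write_partition_file(part, file.path(out_dir, "partition.txt"))
    for (nm in names(topologies))
      ape::write.tree(topologies[[nm]], file.path(out_dir, paste0(nm, ".nwk")))
    log <- stage_log(log, "dataset", t0, n_taxa = nrow(aln), n_sites = ncol(aln),
                     n_loci = nrow(part))

    if (!is.null(cfg$mask_threshold)) {
      t0 <- as.numeric(Sys.time()); stage <- "mask"
      masked <- mask_gap_columns(aln, cfg$mask_threshold, part)
      aln <- masked$alignment; part <- masked$partition
      write_fasta_alignment(aln, file.path(out_dir, "alignment_masked.fasta"))
      log <- stage_log(log, "mask", t0, threshold = cfg$mask_threshold,
                       n_sites = ncol(aln))
    }

    t0 <- as.numeric(Sys.time()); stage <- "fit"
    free <- if (cfg$fit_model) list() else
      list(rates = FALSE, gamma_shape = FALSE, p_inv = FALSE)
    m <- site_lnl_matrix(aln, topologies, model, free = free)
    write_site_lnl_tsv(m, file.path(out_dir, "site_lnl.tsv"))
    log <- stage_log(log, "fit", t0,
                     logLik = stats::setNames(as.list(rowSums(m)), rownames(m)))

    t0 <- as.numeric(Sys.time()); stage <- "signal"
    dis <- signal_dissection(m, part, strong = cfg$strong,
                             moderate = cfg$moderate)
    for (nm in names(dis$pairs))
      write_dlnl_tsv(dis$pairs[[nm]],
                     file.path(out_dir, paste0("dlnl_", nm, ".tsv")))
    utils::write.table(dis$support, file.path(out_dir, "locus_support.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- do.call(rbind, lapply(dis$pairs, summarize_comparison))
    utils::write.table(summ, file.path(out_dir, "signal_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <- stage_log(log, "signal", t0)

    t0 <- as.numeric(Sys.time()); stage <- "tests"
    tst <- topology_tests(m, n = cfg$n_rell, seed = cfg$seed)
    utils::write.table(as.data.frame(tst),
                       file.path(out_dir, "topology_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <- stage_log(log, "tests", t0, n_rell = cfg$n_rell)

    stage <- "manifest"
    outputs <- setdiff(dir(out_dir), "manifest.json")
    manifest <- list(
      package = "plastosig",
      version = as.character(utils::packageVersion("plastosig")),
      seed = cfg$seed,
      config = cfg[!vapply(cfg, is.null, TRUE)],
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(file.path(out_dir, outputs))), outputs)),
      stages = log)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(alignment = aln, partition = part, lnl_matrix = m,
                   dissection = dis, tests = tst, manifest = manifest))
  }, error = on_fail)
}
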