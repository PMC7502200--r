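#' Configuration of an end-to-end pipeline run
#'
#' Either paths to real inputs (counts + metadata, optionally gene models,
#' conservation wig, signal bedGraphs) or a \code{\link{sim_config}} must
#' be provided.
#'
#' @param sim a \code{\link{sim_config}} to generate synthetic inputs, or
#'   NULL.
#' @param counts,meta paths to a counts TSV and metadata TSV (used when
#'   \code{sim} is NULL).
#' @param outdir output directory for tables and the manifest.
#' @param seed master seed; fanned out to per-stage child seeds via
#'   \code{\link{child_seed}}.
#' @param min_reads,min_genes,min_mean_cpm QC and expression filter
#'   thresholds.
#' @param top_frac top fraction for stage-specific and hourglass gene
#'   sets.
#' @param n_boot bootstrap replicates for stage medians and the TPI CI.
#' @param subsample_n,subsample_reps equal-n subsampling parameters.
#' @param protect_stage protect stage during batch correction.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(sim = NULL, counts = NULL, meta = NULL,
                       outdir = tempfile("devnoise_run_"), seed = 1L,
                       min_reads = 300000, min_genes = 4500,
                       min_mean_cpm = 1, top_frac = 0.1, n_boot = 500L,
                       subsample_n = 8L, subsample_reps = 500L,
                       protect_stage = TRUE) {
  if (is.null(sim) && (is.null(counts) || is.null(meta))) {
    stop("provide either a sim_config or paths to counts and meta",
         call. = FALSE)
  }
  structure(list(sim = sim, counts = counts, meta = meta, outdir = outdir,
                 seed = as.integer(seed), min_reads = min_reads,
                 min_genes = min_genes, min_mean_cpm = min_mean_cpm,
                 top_frac = top_frac, n_boot = as.integer(n_boot),
                 subsample_n = as.integer(subsample_n),
                 subsample_reps = as.integer(subsample_reps),
                 protect_stage = protect_stage),
            class = "run_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

matrix_tsv <- function(m, path, id = "gene_id") {
  rn <- rownames(m)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(m)))
  df <- data.frame(rn, m, check.names = FALSE)
  names(df)[1L] <- id
  write_tsv(df, path)
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> QC -> gene filter -> normalize -> batch
#' correct -> MDS / arrested-sample flagging -> variability table and stage
#' comparisons -> bootstrap and equal-n subsampling -> stage-specific and
#' hourglass gene sets -> (when a genome is available) promoter
#' conservation, TPI with CI, and histone Z-signal analyses. Every
#' intermediate table is written under \code{config$outdir} and a JSON
#' manifest records the seed, thresholds, filter survival counts, and a
#' digest per output file; a rerun with the same configuration reproduces
#' every output bit-identically.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  files <- character()
  step <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  bundle <- NULL; truth <- NULL
  if (!is.null(config$sim)) {
    sim <- step("simulate", {
      cfg <- config$sim
      cfg$seed <- child_seed(config$seed, "simulate")
      class(cfg) <- "sim_config"
      simulate_counts(cfg)
    })
    counts <- sim$counts; meta <- sim$meta; truth <- sim$truth
    bundle <- step("genome", simulate_genome(truth$config, truth))
    truth <- bundle$truth
  } else {
    counts <- step("load", read_counts(config$counts))
    meta <- step("load", read_sample_meta(config$meta))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]

  keep_samples <- step("qc_filter",
                       qc_filter(counts, config$min_reads,
                                 config$min_genes))
  counts_qc <- counts[, keep_samples, drop = FALSE]
  meta_qc <- meta[match(keep_samples, meta$sample_id), , drop = FALSE]
  keep_genes <- step("filter_genes",
                     filter_genes(counts_qc, config$min_mean_cpm))
  counts_f <- counts_qc[keep_genes, , drop = FALSE]

  expr_n <- step("normalize", normalize_counts(counts_f))
  expr <- step("correct_batch",
               correct_batch(expr_n, meta_qc, config$protect_stage))
  files <- c(files, matrix_tsv(expr, out("expr.tsv")))

  emb <- step("mds", mds_embed(expr))
  files <- c(files, matrix_tsv(emb, out("mds.tsv"), id = "sample_id"))

  flags <- NULL
  if (!is.null(truth)) {
    ref <- log2(truth$arrested_profile[rownames(expr)] /
                  sum(truth$arrested_profile) * 1e6 + 0.5)
    meiosis <- truth$genes$gene_id[truth$genes$meiosis]
    flags <- step("flag_unfertilized",
                  flag_unfertilized(expr, ref, meiosis, embedding = emb))
    files <- c(files, write_tsv(flags, out("arrested_flags.tsv")))
    keep <- flags$sample_id[!flags$arrested]
    expr <- expr[, keep, drop = FALSE]
    meta_qc <- meta_qc[match(keep, meta_qc$sample_id), , drop = FALSE]
  }

  vtab <- step("variability", variability_table(expr, meta_qc))
  files <- c(files,
             matrix_tsv(vtab$adjusted_sd, out("adjusted_sd.tsv")),
             matrix_tsv(vtab$cv, out("cv.tsv")),
             matrix_tsv(vtab$dm, out("dm.tsv")))
  comp <- step("stage_summary", stage_summary(vtab, "adjusted_sd"))
  files <- c(files, write_tsv(comp$medians, out("stage_medians.tsv")),
             write_tsv(comp$tests, out("stage_tests.tsv")))

  boot <- step("bootstrap", bootstrap_stage_medians(
    expr, meta_qc, vtab$trend, n_boot = config$n_boot,
    seed = child_seed(config$seed, "bootstrap")))
  files <- c(files, matrix_tsv(boot$medians, out("bootstrap_medians.tsv"),
                               id = "rep"))
  sub <- step("subsample", subsample_equal(
    expr, meta_qc, vtab$trend,
    n = min(config$subsample_n, min(table(meta_qc$stage))),
    reps = config$subsample_reps,
    seed = child_seed(config$seed, "subsample")))
  files <- c(files, matrix_tsv(sub, out("subsample_medians.tsv"),
                               id = "rep"))

  sets <- step("stagespec",
               stage_specific_genes(expr, meta_qc,
                                    top_frac = config$top_frac))
  sets_df <- data.frame(
    stage = rep(names(sets), lengths(sets)),
    gene_id = unlist(sets, use.names = FALSE))
  files <- c(files, write_tsv(sets_df, out("stage_specific_genes.tsv")))
  hg <- step("hourglass", hourglass_genes(vtab, config$top_frac))
  files <- c(files, write_tsv(data.frame(gene_id = as.character(hg)),
                              out("hourglass_genes.tsv")))

  cons_comp <- NULL; tpi_res <- NULL; sig_comp <- NULL
  if (!is.null(bundle)) {
    core <- step("promoters", promoter_region(bundle$models, "core"))
    cons <- step("conservation",
                 mean_conservation(core, bundle$conservation))
    cons_comp <- step("stage_set_conservation",
                      stage_set_conservation(sets, cons))
    files <- c(files, write_tsv(cons_comp$medians,
                                out("conservation_medians.tsv")))
    tpi_res <- step("tpi", tpi_ci(
      expr, meta_qc, cons, n_boot = config$n_boot,
      seed = child_seed(config$seed, "tpi")))
    files <- c(files,
               write_tsv(as.data.frame(tpi_res), out("tpi.tsv")))
    zs <- step("chromatin",
               gene_signal_matrix(bundle,
                                  marks = names(bundle$tracks)[1L]))
    sig_comp <- step("stage_signal", stage_signal_summary(zs[[1L]]))
    files <- c(files, write_tsv(sig_comp$medians,
                                out("signal_medians.tsv")))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("devnoise")),
    seed = config$seed,
    thresholds = config[c("min_reads", "min_genes", "min_mean_cpm",
                          "top_frac")],
    n_samples_input = ncol(counts),
    n_samples_qc = length(keep_samples),
    n_samples_analysis = ncol(expr),
    n_genes_input = nrow(counts),
    n_genes_kept = length(keep_genes),
    outputs = lapply(setNames(files, basename(files)), function(f) {
      digest::digest(file = f, algo = "sha256")
    }))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(expr = expr, meta = meta_qc, vtab = vtab,
                 stage_comparison = comp, bootstrap = boot,
                 subsample = sub, stage_sets = sets, hourglass = hg,
                 flags = flags, conservation = cons_comp, tpi = tpi_res,
                 signal = sig_comp, manifest = manifest,
                 outdir = config$outdir))
}
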