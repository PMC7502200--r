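#' Write synthetic-data fixtures to plain-text files
#'
#' Serializes a simulated experiment to the formats the pipeline's readers
#' accept: counts as TSV and MatrixMarket (with gene/sample id sidecars),
#' sample metadata TSV, gene models GFF3, conservation as fixedStep wig
#' (per-base, covered segments only), histone tracks as bedGraph (one file
#' per mark per stage), shape index TSV and, when a truth table is given,
#' gene/sample truth TSVs. All files round-trip through the matching
#' \code{read_*} functions to identical in-memory objects.
#'
#' @param outdir output directory (created if missing).
#' @param counts genes x samples integer matrix.
#' @param meta sample metadata data.frame (\code{sample_id}, \code{stage},
#'   \code{batch}).
#' @param bundle optional \code{genome_bundle}.
#' @param truth optional \code{sim_truth}.
#' @return Invisibly, a character vector of the files written.
#' @export
write_fixtures <- function(outdir, counts, meta, bundle = NULL,
                           truth = NULL) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) {
      stop("cannot create output directory: ", outdir, call. = FALSE)
    }
  }
  files <- character()
  p <- function(f) file.path(outdir, f)

  cdf <- data.frame(gene_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(cdf, p("counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, p("counts.tsv"))

  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"), p("counts.mtx"))
  writeLines(rownames(counts), p("counts_genes.txt"))
  writeLines(colnames(counts), p("counts_samples.txt"))
  files <- c(files, p("counts.mtx"), p("counts_genes.txt"),
             p("counts_samples.txt"))

  m <- meta
  m$stage <- as.character(m$stage)
  m$batch <- as.character(m$batch)
  write.table(m, p("meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, p("meta.tsv"))

  if (!is.null(bundle)) {
    gr <- bundle$models
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- S4Vectors::mcols(gr)$gene_id
    rtracklayer::export(gr, p("genes.gff3"), format = "gff3")
    files <- c(files, p("genes.gff3"))

    write_conservation_wig(bundle$conservation, p("conservation.wig"))
    files <- c(files, p("conservation.wig"))

    for (mk in names(bundle$tracks)) {
      for (st in names(bundle$tracks[[mk]])) {
        f <- p(sprintf("signal_%s_%s.bedGraph", mk, st))
        rtracklayer::export(bundle$tracks[[mk]][[st]], f,
                            format = "bedGraph")
        files <- c(files, f)
      }
    }

    write.table(data.frame(gene_id = names(bundle$shape_index),
                           shape_index = as.numeric(bundle$shape_index)),
                p("shape_index.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, p("shape_index.tsv"))
  }

  if (!is.null(truth)) {
    write.table(truth$genes, p("truth_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    s <- truth$samples
    s$stage <- as.character(s$stage)
    s$batch <- as.character(s$batch)
    write.table(s, p("truth_samples.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(stage = colnames(truth$mu_stage), k = truth$k),
                p("truth_k.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, p("truth_genes.tsv"), p("truth_samples.tsv"),
               p("truth_k.tsv"))
  }
  invisible(files)
}

# fixedStep (step=1, span=1) writer over the covered (non-NA) segments of a
# per-base RleList; values written with 4 decimals
write_conservation_wig <- function(cons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(cons)) {
    r <- cons[[ch]]
    v <- S4Vectors::runValue(r)
    l <- S4Vectors::runLength(r)
    ends <- cumsum(l)
    starts <- ends - l + 1L
    covered <- !is.na(v)
    if (!any(covered)) next
    # group consecutive covered runs into maximal segments
    seg <- cumsum(c(TRUE, diff(covered) != 0L))
    for (sg in unique(seg[covered])) {
      idx <- which(seg == sg & covered)
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1 span=1",
                         ch, starts[idx[1L]]), con)
      vals <- rep(v[idx], l[idx])
      writeLines(sprintf("%.4f", vals), con)
    }
  }
  invisible(path)
}

#' Read a per-base conservation track from a wig file
#'
#' Parses a fixedStep/variableStep wig file and returns a per-base RleList
#' with \code{NA} over uncovered bases, the representation used by
#' \code{\link{mean_conservation}}.
#'
#' @param path wig file.
#' @param chrom_lengths optional named integer vector; chromosomes default
#'   to the last covered base.
#' @return RleList of per-base scores (NA = uncovered).
#' @export
read_conservation_wig <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "wig")
  chroms <- as.character(unique(GenomicRanges::seqnames(gr)))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) {
      max(GenomicRanges::end(gr[GenomicRanges::seqnames(gr) == ch]))
    }, integer(1))
  }
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    vec <- rep(NA_real_, len)
    sub <- gr[GenomicRanges::seqnames(gr) == ch]
    if (length(sub)) {
      w <- GenomicRanges::width(sub)
      pos <- sequence(w, from = GenomicRanges::start(sub))
      vec[pos] <- rep(sub$score, w)
    }
    out[[ch]] <- S4Vectors::Rle(vec)
  }
  methods::as(out, "RleList")
}

#' Read a counts matrix from TSV
#'
#' Expects a header row of sample ids and a first column \code{gene_id}.
#'
#' @param path TSV file.
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}

#' Read a counts matrix from MatrixMarket with id sidecar files
#'
#' @param mtx .mtx file; \code{genes}/\code{samples} default to the sidecar
#'   files written by \code{\link{write_fixtures}}.
#' @param genes,samples paths to one-id-per-line text files.
#' @return Integer matrix, genes x samples.
#' @export
read_counts_mm <- function(mtx,
                           genes = sub("\\.mtx$", "_genes.txt", mtx),
                           samples = sub("\\.mtx$", "_samples.txt", mtx)) {
  m <- as.matrix(Matrix::readMM(mtx))
  storage.mode(m) <- "integer"
  rownames(m) <- readLines(genes)
  colnames(m) <- readLines(samples)
  m
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns \code{sample_id}, \code{stage},
#'   \code{batch}.
#' @param stage_levels optional ordered stage labels; defaults to the sorted
#'   unique stages present.
#' @return data.frame with \code{stage} as an ordered factor and
#'   \code{batch} as a factor.
#' @export
read_sample_meta <- function(path, stage_levels = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (is.null(stage_levels)) stage_levels <- sort(unique(df$stage))
  bad <- setdiff(unique(df$stage), stage_levels)
  if (length(bad)) {
    stop("unknown stage labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$stage <- factor(df$stage, levels = stage_levels, ordered = TRUE)
  df$batch <- factor(df$batch)
  df
}

#' Read gene models from GFF3 or BED
#'
#' @param path GFF3 (records of type \code{gene}, id in \code{ID}) or BED
#'   file (name column taken as gene id).
#' @return GRanges with a \code{gene_id} column, named by gene id. The TSS
#'   is the start for \code{+}-strand and the end for \code{-}-strand genes.
#' @export
read_gene_models <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gff3") {
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[as.character(gr$type) == "gene"]
    }
    gid <- if ("gene_id" %in% names(S4Vectors::mcols(gr))) {
      gr$gene_id
    } else gr$ID
  } else {
    gid <- gr$name
  }
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$gene_id <- as.character(gid)
  names(out) <- out$gene_id
  out
}

#' Read a fixed-window signal track from bedGraph
#'
#' @param path bedGraph file.
#' @return GRanges with a \code{score} column, sorted.
#' @export
read_signal_bedgraph <- function(path) {
  GenomicRanges::sort(rtracklayer::import(path, format = "bedGraph"))
}

#' Read a promoter shape index table
#'
#' @param path TSV with columns \code{gene_id}, \code{shape_index}.
#' @return Named numeric vector (lower = broader promoter).
#' @export
read_shape_index <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  setNames(df$shape_index, df$gene_id)
}
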