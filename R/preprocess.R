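#' Sample quality-control filter
#'
#' Keeps samples with at least \code{min_reads} total counts and at least
#' \code{min_genes} expressed genes (count >= 1); removal uses strict
#' inequality, so a sample at exactly either threshold is kept. Defaults
#' match a single-embryo 3'-end RNA-seq screen: 0.3 million reads and 4500
#' expressed genes.
#'
#' @param counts genes x samples integer matrix.
#' @param min_reads minimum total count per sample (inclusive).
#' @param min_genes minimum number of genes with count >= 1 (inclusive).
#' @return Character vector of retained sample ids, with a per-sample
#'   \code{report} data.frame attached as an attribute.
#' @export
qc_filter <- function(counts, min_reads = 300000, min_genes = 4500) {
  stopifnot(is.matrix(counts), ncol(counts) > 0)
  total <- colSums(counts)
  expressed <- colSums(counts >= 1)
  keep <- total >= min_reads & expressed >= min_genes
  report <- data.frame(sample_id = colnames(counts), total_reads = total,
                       expressed_genes = expressed, qc_pass = keep,
                       row.names = NULL)
  if (!any(keep)) {
    stop("all samples removed by QC; per-sample totals:\n",
         paste(sprintf("  %s: %d reads, %d genes", report$sample_id,
                       report$total_reads, report$expressed_genes),
               collapse = "\n"), call. = FALSE)
  }
  structure(colnames(counts)[keep], report = report)
}

#' Expression filter on mean counts-per-million
#'
#' Removes lowly expressed genes: keeps genes whose mean cpm across samples
#' exceeds 1 (a gene at exactly mean cpm 1 is removed). cpm values are used
#' only for the decision; retained genes keep their original integer counts.
#'
#' @param counts genes x (QC-passed) samples integer matrix.
#' @param min_mean_cpm threshold; keep genes with mean cpm strictly above
#'   it.
#' @return Character vector of retained gene ids.
#' @export
filter_genes <- function(counts, min_mean_cpm = 1) {
  stopifnot(is.matrix(counts))
  total <- colSums(counts)
  if (any(total == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[total == 0], collapse = ", "),
         call. = FALSE)
  }
  cpm <- edgeR::cpm(counts)
  keep <- rowMeans(cpm) > min_mean_cpm
  rownames(counts)[keep]
}

#' Quantile normalization of log2 cpm
#'
#' Converts counts to \code{log2(cpm + pseudocount)} and applies full
#' quantile normalization across samples: each column's sorted values are
#' replaced by the across-column mean of sorted values. With
#' \code{ties = "first"} (the default) ranks are unique and every column
#' ends up with the identical multiset of values, exactly; with
#' \code{ties = "average"} tied entries receive the mean of the values they
#' would have received, the \pkg{limma} convention.
#'
#' @param counts filtered genes x samples integer matrix.
#' @param pseudocount added to cpm before log2.
#' @param ties tie handling, \code{"first"} or \code{"average"}.
#' @return Normalized log2-scale matrix (same dimnames).
#' @export
normalize_counts <- function(counts, pseudocount = 0.5,
                             ties = c("first", "average")) {
  ties <- match.arg(ties)
  if (ncol(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  cpm <- edgeR::cpm(counts)
  lg <- log2(cpm + pseudocount)
  out <- limma::normalizeQuantiles(lg, ties = (ties == "average"))
  dimnames(out) <- dimnames(counts)
  out
}

#' Empirical-Bayes batch correction with post-hoc clipping
#'
#' Location/scale batch adjustment (parametric empirical Bayes: per-gene
#' batch means and variances shrunk toward across-gene priors, then
#' removed), by default protecting the stage factor as a model covariate so
#' stage signal partially aligned with library is not erased. Afterwards the
#' matrix is clipped: any negative corrected value, and any entry whose
#' pre-correction value was exactly 0, is set to 0 — so the result is
#' non-negative and zeros stay zeros.
#'
#' @param expr normalized log2 expression matrix (genes x samples).
#' @param meta sample metadata with \code{batch} and \code{stage} columns
#'   aligned to \code{colnames(expr)}.
#' @param protect_stage include stage as a covariate during correction.
#' @return Corrected, clipped expression matrix.
#' @export
correct_batch <- function(expr, meta, protect_stage = TRUE) {
  stopifnot(is.matrix(expr), nrow(meta) == ncol(expr))
  batch <- factor(meta$batch)
  if (nlevels(batch) < 2L) {
    out <- expr
  } else {
    if (any(table(batch) < 2L)) {
      stop("every batch needs >= 2 samples", call. = FALSE)
    }
    mod <- NULL
    if (protect_stage) {
      stage <- factor(meta$stage)
      tab <- table(batch, stage)
      confounded <- all(rowSums(tab > 0) == 1L)
      if (confounded) {
        stop("batch is confounded 1:1 with stage; ",
             "cannot protect stage as a covariate", call. = FALSE)
      }
      mod <- stats::model.matrix(~stage)
    }
    out <- sva::ComBat(dat = expr, batch = batch, mod = mod,
                       prior.plots = FALSE)
  }
  out[out < 0] <- 0
  out[expr == 0] <- 0
  dimnames(out) <- dimnames(expr)
  out
}

#' Classical MDS embedding of samples on correlation distance
#'
#' Principal-coordinates embedding of the samples with distance
#' \code{d(i, j) = 1 - Pearson correlation} of expression columns. Axis
#' signs are standardized (the largest-magnitude coordinate on each axis is
#' made positive) so the embedding is fully deterministic.
#'
#' @param expr genes x samples expression matrix.
#' @param k number of dimensions.
#' @return samples x k coordinate matrix.
#' @export
mds_embed <- function(expr, k = 2L) {
  if (ncol(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(expr, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression column(s): ",
         paste(colnames(expr)[sds == 0], collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(expr))
  emb <- stats::cmdscale(d, k = k)
  for (j in seq_len(ncol(emb))) {
    i <- which.max(abs(emb[, j]))
    if (emb[i, j] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- colnames(expr)
  emb
}

#' Flag developmentally arrested (unfertilized-egg-like) samples
#'
#' Splits the samples into two clusters by 2-means on the MDS embedding
#' (deterministic initialization at the two most distant samples), then
#' flags the cluster whose mean Pearson correlation with an arrested-egg
#' reference profile exceeds the other cluster's by at least
#' \code{min_cor_gap}; when the clusters do not differ in reference
#' correlation (e.g. no arrested samples present) nothing is flagged. Also
#' reports, per sample, the reference correlation and — when a meiosis gene
#' set is supplied — a meiosis enrichment score: the mean within-sample
#' expression rank of meiosis genes minus the mean rank of all genes.
#'
#' @param expr genes x samples expression matrix.
#' @param reference_profile named per-gene numeric reference (must cover at
#'   least half the genes in \code{expr}).
#' @param meiosis_genes optional character vector of meiosis-related genes.
#' @param embedding optional precomputed MDS embedding; defaults to
#'   \code{mds_embed(expr)}.
#' @param min_cor_gap minimal between-cluster difference in mean reference
#'   correlation required to call the arrested cluster.
#' @return data.frame with \code{sample_id}, \code{ref_cor},
#'   \code{meiosis_score} (NA when no set given), \code{cluster},
#'   \code{arrested} (logical flag).
#' @export
flag_unfertilized <- function(expr, reference_profile, meiosis_genes = NULL,
                              embedding = NULL, min_cor_gap = 0.1) {
  shared <- intersect(rownames(expr), names(reference_profile))
  if (length(shared) < 0.5 * nrow(expr)) {
    stop("reference profile covers < 50% of genes", call. = FALSE)
  }
  ref <- reference_profile[shared]
  ref_cor <- apply(expr[shared, , drop = FALSE], 2L,
                   function(x) stats::cor(x, ref))

  meiosis_score <- rep(NA_real_, ncol(expr))
  if (!is.null(meiosis_genes)) {
    mg <- intersect(meiosis_genes, rownames(expr))
    if (!length(mg)) {
      warning("empty meiosis gene set; score omitted")
    } else {
      rks <- apply(expr, 2L, rank_avg)
      meiosis_score <- colMeans(rks[mg, , drop = FALSE]) - colMeans(rks)
    }
  }

  if (is.null(embedding)) embedding <- mds_embed(expr)
  d <- as.matrix(stats::dist(embedding))
  far <- which(d == max(d), arr.ind = TRUE)[1L, ]
  km <- stats::kmeans(embedding, centers = embedding[far, , drop = FALSE])
  cl <- km$cluster
  m1 <- mean(ref_cor[cl == 1L])
  m2 <- mean(ref_cor[cl == 2L])
  arrested_cluster <- if (abs(m1 - m2) >= min_cor_gap) {
    if (m1 > m2) 1L else 2L
  } else NA_integer_
  data.frame(sample_id = colnames(expr), ref_cor = ref_cor,
             meiosis_score = meiosis_score, cluster = cl,
             arrested = !is.na(arrested_cluster) & cl == arrested_cluster,
             row.names = NULL)
}

#' Per-sample X-to-autosome expression ratio
#'
#' Median expression of X-linked genes divided by the median expression of
#' autosomal genes, per sample — a check that sample clusters are not
#' explained by embryo sex.
#'
#' @param expr genes x samples expression matrix.
#' @param models gene-model GRanges (chromosome assignment), or a
#'   \code{genome_bundle}.
#' @param x_chrom name of the X chromosome.
#' @return Named numeric vector of per-sample ratios.
#' @export
x_autosome_ratio <- function(expr, models, x_chrom = "chrX") {
  if (inherits(models, "genome_bundle")) models <- models$models
  chrom <- as.character(GenomicRanges::seqnames(models))
  gid <- models$gene_id
  xg <- intersect(gid[chrom == x_chrom], rownames(expr))
  ag <- intersect(gid[chrom != x_chrom], rownames(expr))
  if (!length(xg)) stop("no X-linked genes in matrix", call. = FALSE)
  if (!length(ag)) stop("no autosomal genes in matrix", call. = FALSE)
  xmed <- apply(expr[xg, , drop = FALSE], 2L, stats::median)
  amed <- apply(expr[ag, , drop = FALSE], 2L, stats::median)
  xmed / amed
}
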