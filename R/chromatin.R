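#' Mean promoter histone signal per gene
#'
#' Unweighted mean of the scores of all fixed-width track windows that
#' overlap the proximal promoter (TSS +/- \code{half_width}, strand
#' symmetric): interval-map "mean" semantics, so a window counts once
#' regardless of how many bases overlap. Genes whose promoter overlaps no
#' window get NA.
#'
#' @param models gene-model GRanges or \code{genome_bundle}.
#' @param track GRanges with a \code{score} column (35-bp windows).
#' @param half_width promoter half-width in bp.
#' @return Named numeric vector, one mean score per gene.
#' @export
promoter_signal <- function(models, track, half_width = 2000L) {
  if (inherits(models, "genome_bundle")) models <- models$models
  prom <- promoter_region(models, "proximal", half_width = half_width)
  hits <- GenomicRanges::findOverlaps(prom, track)
  out <- rep(NA_real_, length(prom))
  if (length(hits)) {
    sums <- tapply(track$score[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), mean)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  names(out) <- names(prom)
  out
}

#' Intergenic regions: genome minus promoters and gene bodies
#'
#' Complement of the union of all proximal promoters (TSS +/-
#' \code{half_width}) and gene bodies (TSS to TES, i.e. the full gene
#' range); overlapping genes are merged before taking the complement.
#'
#' @param models gene-model GRanges with seqlengths set, or a
#'   \code{genome_bundle}.
#' @param half_width promoter half-width in bp.
#' @return GRanges of merged intergenic intervals.
#' @export
intergenic_regions <- function(models, half_width = 2000L) {
  if (inherits(models, "genome_bundle")) models <- models$models
  sl <- GenomeInfoDb::seqlengths(models)
  if (any(is.na(sl))) stop("gene models need seqlengths", call. = FALSE)
  prom <- promoter_region(models, "proximal", half_width = half_width)
  blocked <- GenomicRanges::reduce(
    c(GenomicRanges::granges(prom, use.mcols = FALSE),
      GenomicRanges::granges(models, use.mcols = FALSE)),
    ignore.strand = TRUE)
  genome <- GenomicRanges::GRanges(
    names(sl), IRanges::IRanges(1L, unname(sl)))
  GenomeInfoDb::seqlengths(genome) <- sl
  inter <- GenomicRanges::setdiff(genome, blocked, ignore.strand = TRUE)
  if (!length(inter)) {
    stop("no intergenic region left (genes tile the genome)",
         call. = FALSE)
  }
  inter
}

#' Z-score a signal track against its intergenic background
#'
#' Computes the mean and SD of the scores of windows fully contained in the
#' intergenic regions and maps every window's score to (x - mu) / sigma —
#' per mark, per stage — so promoter signal becomes comparable across
#' libraries. Windows straddling an intergenic boundary are excluded from
#' mu and sigma (their count is attached as attribute
#' \code{n_boundary_excluded}).
#'
#' @param track GRanges with a \code{score} column.
#' @param intergenic GRanges from \code{\link{intergenic_regions}}.
#' @return The track with Z-scored \code{score}; attributes
#'   \code{intergenic_mean}, \code{intergenic_sd},
#'   \code{n_boundary_excluded}.
#' @export
zscore_track <- function(track, intergenic) {
  within <- GenomicRanges::countOverlaps(track, intergenic,
                                         type = "within") > 0L
  touching <- GenomicRanges::countOverlaps(track, intergenic) > 0L
  if (sum(within) < 2L) {
    stop("need >= 2 windows fully inside intergenic regions",
         call. = FALSE)
  }
  x <- track$score[within]
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (sigma == 0) stop("intergenic signal SD is zero", call. = FALSE)
  out <- track
  out$score <- (track$score - mu) / sigma
  attr(out, "intergenic_mean") <- mu
  attr(out, "intergenic_sd") <- sigma
  attr(out, "n_boundary_excluded") <- sum(touching & !within)
  out
}

#' Z-scored promoter signal for every mark and stage
#'
#' Convenience wrapper: Z-scores each track of a \code{genome_bundle}
#' against the intergenic background and computes the per-gene mean
#' promoter signal.
#'
#' @param bundle a \code{genome_bundle}.
#' @param marks marks to process (default all tracks present).
#' @param half_width promoter half-width in bp.
#' @return Named list per mark of genes x stages matrices of Z-scored
#'   promoter means.
#' @export
gene_signal_matrix <- function(bundle, marks = names(bundle$tracks),
                               half_width = 2000L) {
  inter <- intergenic_regions(bundle$models, half_width = half_width)
  out <- list()
  for (mk in marks) {
    stages <- names(bundle$tracks[[mk]])
    m <- vapply(stages, function(st) {
      z <- zscore_track(bundle$tracks[[mk]][[st]], inter)
      promoter_signal(bundle$models, z, half_width = half_width)
    }, numeric(length(bundle$models)))
    rownames(m) <- names(bundle$models)
    out[[mk]] <- m
  }
  out
}

#' Spearman correlation between promoter signal and a gene feature
#'
#' Two-sided Spearman rank correlation on genes with both values (e.g.
#' across-stage mean histone signal versus across-stage mean expression
#' variability, or versus promoter conservation).
#'
#' @param signal named per-gene numeric (aggregated, e.g. across-stage
#'   mean).
#' @param feature named per-gene numeric.
#' @return List: \code{rho}, \code{p}, \code{n}.
#' @export
signal_feature_correlation <- function(signal, feature) {
  shared <- intersect(names(signal), names(feature))
  x <- signal[shared]; y <- feature[shared]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10L) stop("fewer than 10 complete genes", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Spearman partial correlation
#'
#' Rank-transforms x, y and the control variable (average ties) and returns
#' the first-order partial correlation
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}
#' on the ranked data — e.g. histone signal versus expression variability
#' controlling for promoter shape. Complete cases only.
#'
#' @param x,y,control numeric vectors of equal length (or named per-gene
#'   vectors, matched on shared names).
#' @return List: \code{rho} (partial Spearman), \code{n}.
#' @export
partial_spearman <- function(x, y, control) {
  if (!is.null(names(x)) && !is.null(names(y)) &&
      !is.null(names(control))) {
    shared <- Reduce(intersect, list(names(x), names(y), names(control)))
    x <- x[shared]; y <- y[shared]; control <- control[shared]
  }
  stopifnot(length(x) == length(y), length(x) == length(control))
  ok <- stats::complete.cases(x, y, control)
  x <- x[ok]; y <- y[ok]; z <- control[ok]
  rx <- rank_avg(x); ry <- rank_avg(y); rz <- rank_avg(z)
  r_xy <- stats::cor(rx, ry)
  r_xz <- stats::cor(rx, rz)
  r_yz <- stats::cor(ry, rz)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("control is perfectly rank-correlated with x or y; ",
         "partial correlation undefined", call. = FALSE)
  }
  rho <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  list(rho = rho, n = length(x))
}

#' Stage distributions of Z-scored promoter signal
#'
#' Per-stage distribution of per-gene promoter Z-scores with medians and
#' pairwise Wilcoxon-BH tests; stages whose signal is entirely missing are
#' omitted with a note.
#'
#' @param zsignal genes x stages matrix of Z-scored promoter means (one
#'   mark), e.g. one element of \code{\link{gene_signal_matrix}}.
#' @return \code{stage_comparison} as in \code{\link{stage_summary}}.
#' @export
stage_signal_summary <- function(zsignal) {
  vals <- lapply(seq_len(ncol(zsignal)), function(j) {
    v <- zsignal[, j]
    v[is.finite(v)]
  })
  names(vals) <- colnames(zsignal)
  absent <- names(vals)[lengths(vals) == 0L]
  if (length(absent)) {
    message("stage(s) without signal omitted: ",
            paste(absent, collapse = ", "))
  }
  vals <- vals[lengths(vals) > 0L]
  medians <- data.frame(stage = names(vals),
                        median = vapply(vals, stats::median, numeric(1)),
                        n_genes = lengths(vals), row.names = NULL)
  structure(list(medians = medians,
                 tests = if (length(vals) > 1L) pairwise_wilcox(vals)
                         else NULL,
                 metric = "signal_z"),
            class = "stage_comparison")
}
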