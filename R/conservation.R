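#' Promoter regions around the representative TSS
#'
#' Strand-aware promoter intervals for each gene model. The \code{core}
#' flavour covers -49..+10 relative to the TSS (60 bp, the experimentally
#' validated core-promoter convention); \code{w200}, \code{w400} and
#' \code{w1k} are 200-bp, 400-bp and 1-kb windows centred on the TSS;
#' \code{proximal} is the strand-symmetric +/- \code{half_width} window
#' used for histone signal. Regions extending past chromosome bounds are
#' clipped and the clipped gene ids reported in attribute \code{clipped}.
#'
#' @param models gene-model GRanges (TSS = start on \code{+}, end on
#'   \code{-}) with seqlengths set, or a \code{genome_bundle}.
#' @param flavour one of \code{"core"}, \code{"w200"}, \code{"w400"},
#'   \code{"w1k"}, \code{"proximal"}.
#' @param half_width half-width of the \code{proximal} flavour (bp).
#' @return GRanges of promoter regions (named by gene id).
#' @export
promoter_region <- function(models,
                            flavour = c("core", "w200", "w400", "w1k",
                                        "proximal"),
                            half_width = 2000L) {
  flavour <- match.arg(flavour)
  if (inherits(models, "genome_bundle")) models <- models$models
  str <- as.character(GenomicRanges::strand(models))
  if (any(str == "*")) stop("unknown strand in gene models", call. = FALSE)
  tss <- ifelse(str == "+", GenomicRanges::start(models),
                GenomicRanges::end(models))
  if (flavour == "core") {
    # -49..+10 inclusive of the TSS base: 60 bp, mirrored on minus strand
    lo <- ifelse(str == "+", tss - 49L, tss - 10L)
    hi <- ifelse(str == "+", tss + 10L, tss + 49L)
  } else {
    hw <- switch(flavour, w200 = 100L, w400 = 200L, w1k = 500L,
                 proximal = as.integer(half_width))
    lo <- tss - hw
    hi <- tss + hw - 1L
  }
  sl <- GenomeInfoDb::seqlengths(models)
  chrom <- as.character(GenomicRanges::seqnames(models))
  lim <- sl[chrom]
  lim[is.na(lim)] <- .Machine$integer.max
  lo_c <- pmax(lo, 1L)
  hi_c <- pmin(hi, unname(lim))
  clipped <- models$gene_id[lo_c != lo | hi_c != hi]
  if (length(clipped)) {
    message(length(clipped), " promoter region(s) clipped at chromosome",
            " bounds")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo_c, hi_c),
                               strand = str, gene_id = models$gene_id)
  sl_known <- sl[!is.na(sl)]
  keep <- intersect(GenomeInfoDb::seqlevels(gr), names(sl_known))
  GenomeInfoDb::seqlengths(gr)[keep] <- sl_known[keep]
  names(gr) <- models$gene_id
  attr(gr, "clipped") <- clipped
  gr
}

#' Mean per-base conservation over regions
#'
#' Unweighted mean of per-base conservation scores over each region;
#' uncovered bases (NA in the track) are excluded from numerator and
#' denominator. A fully uncovered region yields NA. The per-region
#' uncovered fraction is attached as attribute \code{uncovered_fraction}.
#'
#' @param regions GRanges (e.g. from \code{\link{promoter_region}}).
#' @param track per-base RleList in [0, 1] (NA = uncovered), e.g. from
#'   \code{\link{read_conservation_wig}} or a \code{genome_bundle}'s
#'   \code{conservation}.
#' @return Named numeric vector of mean scores per region.
#' @export
mean_conservation <- function(regions, track) {
  if (inherits(track, "genome_bundle")) track <- track$conservation
  out <- rep(NA_real_, length(regions))
  uncov <- rep(NA_real_, length(regions))
  chroms <- as.character(GenomicRanges::seqnames(regions))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    if (!ch %in% names(track)) next
    r <- track[[ch]]
    st <- pmax(GenomicRanges::start(regions)[idx], 1L)
    en <- pmin(GenomicRanges::end(regions)[idx], length(r))
    v <- IRanges::Views(r, start = st, end = en)
    out[idx] <- IRanges::viewMeans(v, na.rm = TRUE)
    uncov[idx] <- vapply(seq_along(v), function(i) {
      x <- v[[i]]
      sum(is.na(x)) / length(x)
    }, numeric(1))
  }
  out[is.nan(out)] <- NA_real_
  names(out) <- names(regions)
  attr(out, "uncovered_fraction") <- setNames(uncov, names(regions))
  out
}

#' Promoter conservation distributions of stage-specific gene sets
#'
#' Per-stage conservation score vectors, medians and all pairwise Wilcoxon
#' rank-sum tests (BH-corrected) over the stage-specific gene sets. Stages
#' with an empty set are marked absent and skipped.
#'
#' @param stage_sets named list of gene-id vectors (from
#'   \code{\link{stage_specific_genes}}).
#' @param scores named per-gene numeric scores.
#' @return List of class \code{stage_comparison}: \code{medians},
#'   \code{tests}, plus \code{values} (per-stage score vectors) and
#'   \code{absent} (stages with no scored genes).
#' @export
stage_set_conservation <- function(stage_sets, scores) {
  vals <- lapply(stage_sets, function(g) {
    v <- scores[intersect(g, names(scores))]
    v[is.finite(v)]
  })
  absent <- names(vals)[lengths(vals) == 0L]
  vals <- vals[lengths(vals) > 0L]
  medians <- data.frame(stage = names(vals),
                        median = vapply(vals, stats::median, numeric(1)),
                        n_genes = lengths(vals), row.names = NULL)
  structure(list(medians = medians, tests = pairwise_wilcox(vals),
                 values = vals, absent = absent,
                 metric = "conservation"),
            class = "stage_comparison")
}

per_stage_weights <- function(expr, meta) {
  mom <- stage_moments(expr, meta)
  mom$mean
}

#' Transcriptome index of promoter conservation (TPI)
#'
#' Expression-weighted mean conservation per stage:
#' \deqn{TPI_s = \sum_i phastCons_i e_{is} / \sum_i e_{is}}
#' where \eqn{e_{is}} is gene i's expression level at stage s (the
#' per-stage mean of the log-scale, non-negative expression matrix) and the
#' sums run over genes with a defined conservation score.
#'
#' @param expr genes x samples non-negative log-scale expression matrix.
#' @param meta sample metadata aligned to columns (\code{stage}).
#' @param scores named per-gene conservation scores; NA-scored genes are
#'   excluded from both sums.
#' @return data.frame of class \code{tpi_result}: \code{stage},
#'   \code{tpi}, \code{n_genes}.
#' @export
tpi <- function(expr, meta, scores) {
  e <- per_stage_weights(expr, meta)
  shared <- intersect(rownames(e), names(scores))
  sc <- scores[shared]
  ok <- is.finite(sc)
  shared <- shared[ok]; sc <- sc[ok]
  e <- e[shared, , drop = FALSE]
  if (any(e < 0)) stop("expression weights must be non-negative",
                       call. = FALSE)
  denom <- colSums(e)
  val <- as.numeric(crossprod(e, sc)) / denom
  val[denom == 0] <- NA_real_
  structure(data.frame(stage = colnames(e), tpi = val,
                       n_genes = length(shared), row.names = NULL),
            class = c("tpi_result", "data.frame"))
}

#' Gene-bootstrap confidence intervals for the TPI
#'
#' Resamples gene ids with replacement \code{n_boot} times, recomputes the
#' TPI per stage for every resample and reports the empirical 2.5% and
#' 97.5% percentiles (for \code{conf = 0.95}) alongside the point
#' estimates.
#'
#' @inheritParams tpi
#' @param n_boot number of bootstrap resamples (< 100 warns).
#' @param conf confidence level.
#' @param seed integer seed for the resampling.
#' @return data.frame of class \code{tpi_result}: \code{stage}, \code{tpi},
#'   \code{ci_lo}, \code{ci_hi}, \code{n_genes}; the bootstrap matrix
#'   (n_boot x stages) is attached as attribute \code{boot}.
#' @export
tpi_ci <- function(expr, meta, scores, n_boot = 10000L, conf = 0.95,
                   seed = 1L) {
  if (n_boot < 100L) warning("n_boot < 100: confidence interval unstable")
  e <- per_stage_weights(expr, meta)
  shared <- intersect(rownames(e), names(scores))
  sc <- scores[shared]
  ok <- is.finite(sc)
  shared <- shared[ok]; sc <- unname(sc[ok])
  if (length(shared) < 10L) stop("need >= 10 scored genes", call. = FALSE)
  e <- e[shared, , drop = FALSE]
  point <- tpi(expr, meta, scores)

  n <- length(shared)
  boot <- matrix(NA_real_, n_boot, ncol(e),
                 dimnames = list(NULL, colnames(e)))
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    for (s in seq_len(ncol(e))) {
      es <- matrix(e[, s][idx], n, n_boot)
      ss <- matrix(sc[idx], n, n_boot)
      boot[, s] <- colSums(ss * es) / colSums(es)
    }
  })
  a <- (1 - conf) / 2
  point$ci_lo <- apply(boot, 2L, stats::quantile, probs = a, na.rm = TRUE)
  point$ci_hi <- apply(boot, 2L, stats::quantile, probs = 1 - a,
                       na.rm = TRUE)
  attr(point, "boot") <- boot
  point
}
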