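#' Fit the global mean-SD polynomial trend
#'
#' Ordinary least squares of per-gene global SD on orthogonal polynomials of
#' per-gene global mean expression. The degree is grown from 1 while the
#' nested-model F-test (ANOVA) of degree d versus d - 1 improves the fit at
#' \code{p < alpha}; if no degree-1 improvement over the intercept is
#' significant, the intercept-only model (degree 0) is kept. Predictions
#' used as divisors are floored at \code{eps}.
#'
#' @param global_mean,global_sd per-gene numeric vectors.
#' @param alpha significance level for the nested F-test.
#' @param max_degree largest degree tried; reaching it while the improvement
#'   is still significant keeps \code{max_degree} with a warning.
#' @param eps floor applied by \code{predict} when \code{floor = TRUE}.
#' @return Object of class \code{sd_trend}: \code{fit} (the lm),
#'   \code{degree}, \code{eps}.
#' @export
fit_sd_trend <- function(global_mean, global_sd, alpha = 0.05,
                         max_degree = 10L, eps = 1e-6) {
  ok <- is.finite(global_mean) & is.finite(global_sd)
  if (sum(ok) < 20L) stop("need >= 20 genes with finite values",
                          call. = FALSE)
  df <- data.frame(m = global_mean[ok], s = global_sd[ok])
  max_degree <- min(max_degree, length(unique(df$m)) - 1L)
  fit_prev <- stats::lm(s ~ 1, data = df)
  degree <- 0L
  for (d in seq_len(max_degree)) {
    fml <- stats::as.formula(sprintf("s ~ poly(m, %d)", d),
                             env = environment())
    fit_d <- stats::lm(fml, data = df)
    p <- stats::anova(fit_prev, fit_d)[2L, "Pr(>F)"]
    if (is.na(p) || p >= alpha) break
    fit_prev <- fit_d
    degree <- d
    if (d == max_degree) {
      warning("trend improvement still significant at max_degree = ",
              max_degree)
    }
  }
  structure(list(fit = fit_prev, degree = degree, eps = eps),
            class = "sd_trend")
}

#' @rdname fit_sd_trend
#' @param object an \code{sd_trend}.
#' @param newdata numeric vector of global means.
#' @param floor floor predictions at \code{eps} (for use as divisors).
#' @param ... unused.
#' @export
predict.sd_trend <- function(object, newdata, floor = TRUE, ...) {
  p <- unname(stats::predict(object$fit,
                             newdata = data.frame(m = newdata)))
  if (floor) p <- pmax(p, object$eps)
  p
}

#' @export
#' @method print sd_trend
print.sd_trend <- function(x, ...) {
  cat("sd_trend: polynomial degree", x$degree, "\n")
  invisible(x)
}

stage_groups <- function(meta) {
  split(seq_len(nrow(meta)), meta$stage, drop = FALSE)
}

# per-stage population-SD and mean matrices; stages with < 2 samples are
# dropped with a warning
stage_moments <- function(expr, meta) {
  grp <- stage_groups(meta)
  sizes <- lengths(grp)
  if (any(sizes > 0L & sizes < 2L)) {
    warning("stage(s) with < 2 samples excluded: ",
            paste(names(grp)[sizes == 1L], collapse = ", "))
  }
  grp <- grp[sizes >= 2L]
  mean_m <- vapply(grp, function(j) rowMeans(expr[, j, drop = FALSE]),
                   numeric(nrow(expr)))
  sd_m <- vapply(grp, function(j) row_sd_pop(expr[, j, drop = FALSE]),
                 numeric(nrow(expr)))
  rownames(mean_m) <- rownames(sd_m) <- rownames(expr)
  list(mean = mean_m, sd = sd_m)
}

#' Adjusted SD: observed stage SD over trend-predicted global SD
#'
#' For each gene and stage, the population SD (divisor n) of the gene's
#' expression over that stage's samples divided by the gene's global SD as
#' predicted from its global mean by the polynomial trend — a variability
#' metric independent of expression level by construction.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param meta sample metadata aligned to columns (\code{stage}).
#' @param trend an \code{\link{fit_sd_trend}} object; fitted on the global
#'   moments of \code{expr} when NULL.
#' @return genes x stages matrix of adjusted SD values.
#' @export
adjusted_sd <- function(expr, meta, trend = NULL) {
  if (is.null(trend)) {
    trend <- fit_sd_trend(rowMeans(expr), row_sd_pop(expr))
  }
  mom <- stage_moments(expr, meta)
  pred <- predict(trend, rowMeans(expr), floor = TRUE)
  out <- mom$sd / pred
  dimnames(out) <- dimnames(mom$sd)
  out
}

#' Per-stage coefficient of variation
#'
#' \code{CV_gs = SD_gs / mean_gs} with population SD; entries with stage
#' mean 0 are undefined and returned as NA.
#'
#' @inheritParams adjusted_sd
#' @return genes x stages matrix of CV values (NA where masked).
#' @export
cv_by_stage <- function(expr, meta) {
  mom <- stage_moments(expr, meta)
  out <- mom$sd / mom$mean
  out[mom$mean == 0] <- NA_real_
  out
}

# window assignment for distance-to-median: sliding windows of `window`
# genes with `overlap` overlap over mean-ranked genes; each gene goes to
# the window whose centre gene (the ceil(w/2)-th member) is nearest its
# rank, ties to the lower window
dm_windows <- function(n, window = 50L, overlap = 25L) {
  if (overlap >= window) stop("window must exceed overlap", call. = FALSE)
  if (n <= window) {
    return(list(starts = 1L, members = list(seq_len(n)),
                assign = rep(1L, n)))
  }
  step <- window - overlap
  starts <- seq.int(1L, n - window + 1L, by = step)
  members <- lapply(starts, function(s) seq.int(s, s + window - 1L))
  centres <- starts + as.integer(ceiling(window / 2)) - 1L
  dist <- abs(outer(seq_len(n), centres, "-"))
  assign <- apply(dist, 1L, which.min)  # which.min takes the first tie
  list(starts = starts, members = members, assign = assign)
}

#' Distance to median (DM) of the squared CV
#'
#' Genes are ordered by global mean expression (ascending) and grouped into
#' sliding windows of \code{window} genes with \code{overlap} genes of
#' overlap. A gene's DM at stage s is its stage-specific log10 squared CV
#' minus the median global log10 squared CV of the genes in its window
#' (the window whose centre is nearest the gene's rank; ties go to the
#' lower window). Genes with zero global CV are excluded; entries with zero
#' stage CV are NA.
#'
#' @inheritParams adjusted_sd
#' @param window,overlap window size and overlap in genes.
#' @return genes x stages matrix of DM values; excluded genes are absent,
#'   and the gene-to-window assignment is attached as attribute
#'   \code{window_assign}.
#' @export
distance_to_median <- function(expr, meta, window = 50L, overlap = 25L) {
  gmean <- rowMeans(expr)
  gsd <- row_sd_pop(expr)
  gcv2 <- (gsd / gmean)^2
  ok <- is.finite(gcv2) & gcv2 > 0
  if (!all(ok)) {
    message(sum(!ok), " gene(s) with zero/undefined global CV excluded",
            " from DM")
  }
  expr <- expr[ok, , drop = FALSE]
  gmean <- gmean[ok]
  gcv2 <- gcv2[ok]

  ord <- order(gmean)
  n <- length(ord)
  w <- dm_windows(n, window, overlap)
  lg_global <- log10(gcv2)[ord]
  win_median <- vapply(w$members,
                       function(m) stats::median(lg_global[m]),
                       numeric(1))
  gene_median <- win_median[w$assign]        # in rank order
  gene_median <- gene_median[order(ord)]     # back to gene order

  cvs <- cv_by_stage(expr, meta)
  lg_stage <- log10(cvs^2)
  lg_stage[!is.finite(lg_stage)] <- NA_real_
  out <- lg_stage - gene_median
  assign_gene <- integer(n)
  assign_gene[ord] <- w$assign
  attr(out, "window_assign") <- setNames(assign_gene, rownames(expr))
  out
}

#' Per-gene per-stage variability table
#'
#' Convenience wrapper computing global moments, the mean-SD trend and all
#' three variability metrics at once.
#'
#' @inheritParams adjusted_sd
#' @param window,overlap passed to \code{\link{distance_to_median}}.
#' @return Object of class \code{variability_table}: \code{global}
#'   (data.frame: gene_id, mean, sd, predicted_sd), \code{stage_mean},
#'   \code{stage_sd}, \code{cv}, \code{dm}, \code{adjusted_sd} (genes x
#'   stages matrices), \code{trend}.
#' @export
variability_table <- function(expr, meta, trend = NULL, window = 50L,
                              overlap = 25L) {
  gmean <- rowMeans(expr)
  gsd <- row_sd_pop(expr)
  if (is.null(trend)) trend <- fit_sd_trend(gmean, gsd)
  mom <- stage_moments(expr, meta)
  structure(list(
    global = data.frame(gene_id = rownames(expr), mean = gmean, sd = gsd,
                        predicted_sd = predict(trend, gmean),
                        row.names = NULL),
    stage_mean = mom$mean, stage_sd = mom$sd,
    cv = cv_by_stage(expr, meta),
    dm = distance_to_median(expr, meta, window, overlap),
    adjusted_sd = adjusted_sd(expr, meta, trend),
    trend = trend), class = "variability_table")
}

#' @export
#' @method print variability_table
print.variability_table <- function(x, ...) {
  cat("variability_table:", nrow(x$adjusted_sd), "genes x",
      ncol(x$adjusted_sd), "stages; trend degree", x$trend$degree, "\n")
  invisible(x)
}

get_metric <- function(vtab, metric) {
  if (inherits(vtab, "variability_table")) {
    if (!metric %in% c("adjusted_sd", "dm", "cv")) {
      stop("unknown metric: ", metric, call. = FALSE)
    }
    vtab[[metric]]
  } else {
    stopifnot(is.matrix(vtab))
    vtab
  }
}

#' Stage medians and pairwise Wilcoxon comparisons of a variability metric
#'
#' Per-stage median of the per-gene metric plus all pairwise two-sided
#' Wilcoxon rank-sum tests between stages, Benjamini-Hochberg corrected
#' over the set of pairs.
#'
#' @param vtab a \code{\link{variability_table}} or a genes x stages metric
#'   matrix.
#' @param metric one of \code{"adjusted_sd"}, \code{"dm"}, \code{"cv"}
#'   (ignored when a matrix is given).
#' @param genes optional gene subset (e.g. maternal-excluded or
#'   always-expressed re-analyses).
#' @return List of class \code{stage_comparison}: \code{medians}
#'   (data.frame stage, median, n_genes) and \code{tests} (pairwise table
#'   with raw and BH-adjusted p).
#' @export
stage_summary <- function(vtab, metric = "adjusted_sd", genes = NULL) {
  m <- get_metric(vtab, metric)
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(m))
    if (!length(genes)) stop("gene subset empty", call. = FALSE)
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 2L) stop("need >= 2 stages", call. = FALSE)
  vals <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    v[is.finite(v)]
  })
  names(vals) <- colnames(m)
  medians <- data.frame(stage = colnames(m),
                        median = vapply(vals, stats::median, numeric(1)),
                        n_genes = lengths(vals), row.names = NULL)
  structure(list(medians = medians, tests = pairwise_wilcox(vals),
                 metric = if (is.character(metric)) metric else "custom"),
            class = "stage_comparison")
}

#' @export
#' @method print stage_comparison
print.stage_comparison <- function(x, ...) {
  cat("stage_comparison (", x$metric, ")\n", sep = "")
  print(x$medians)
  invisible(x)
}

#' Bootstrap distribution of per-stage median adjusted SD
#'
#' Per replicate, resamples \code{n} samples with replacement within each
#' stage, recomputes the adjusted SD (against the fixed full-data trend
#' unless \code{refit_trend}) and stores the median across genes; the
#' per-stage vectors of bootstrap medians are compared by pairwise Wilcoxon
#' tests.
#'
#' @inheritParams adjusted_sd
#' @param n_boot number of bootstrap replicates.
#' @param n common per-stage sample size; defaults to the smallest stage.
#' @param refit_trend refit the mean-SD trend inside each replicate.
#' @param seed integer seed for the resampling.
#' @return List: \code{medians} (n_boot x stages matrix), \code{tests}
#'   (pairwise Wilcoxon-BH on the bootstrap medians).
#' @export
bootstrap_stage_medians <- function(expr, meta, trend = NULL,
                                    n_boot = 500L, n = NULL,
                                    refit_trend = FALSE, seed = 1L) {
  grp <- stage_groups(meta)
  grp <- grp[lengths(grp) > 0L]
  if (is.null(n)) n <- min(lengths(grp))
  if (n < 2L) stop("common stage size must be >= 2", call. = FALSE)
  if (is.null(trend)) {
    trend <- fit_sd_trend(rowMeans(expr), row_sd_pop(expr))
  }
  stages <- names(grp)
  med <- matrix(NA_real_, n_boot, length(stages),
                dimnames = list(NULL, stages))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(grp, function(j) sample(j, n, replace = TRUE)))
      sub_meta <- meta[idx, , drop = FALSE]
      sub_expr <- expr[, idx, drop = FALSE]
      tr <- if (refit_trend) {
        fit_sd_trend(rowMeans(sub_expr), row_sd_pop(sub_expr))
      } else trend
      a <- adjusted_sd(sub_expr, sub_meta, tr)
      med[b, colnames(a)] <- apply(a, 2L, stats::median, na.rm = TRUE)
    }
  })
  vals <- lapply(seq_len(ncol(med)), function(j) med[, j])
  names(vals) <- stages
  list(medians = med, tests = pairwise_wilcox(vals))
}

#' Equal-n subsampling of stages without replacement
#'
#' Per repetition, draws \code{n} samples per stage without replacement,
#' recomputes the stage adjusted SD against the fixed global trend and
#' records the median across genes — a robustness check that stage-median
#' differences are not driven by unequal stage sizes.
#'
#' @inheritParams bootstrap_stage_medians
#' @param n samples drawn per stage (every stage must have at least n).
#' @param reps number of repetitions (0 gives an empty result).
#' @return reps x stages matrix of median adjusted SD.
#' @export
subsample_equal <- function(expr, meta, trend = NULL, n = 8L, reps = 500L,
                            seed = 1L) {
  grp <- stage_groups(meta)
  grp <- grp[lengths(grp) > 0L]
  small <- names(grp)[lengths(grp) < n]
  if (length(small)) {
    stop("stage(s) smaller than n = ", n, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  if (is.null(trend)) {
    trend <- fit_sd_trend(rowMeans(expr), row_sd_pop(expr))
  }
  med <- matrix(NA_real_, reps, length(grp),
                dimnames = list(NULL, names(grp)))
  if (reps == 0L) return(med)
  with_seed(seed, {
    for (b in seq_len(reps)) {
      idx <- unlist(lapply(grp, function(j) sample(j, n, replace = FALSE)))
      a <- adjusted_sd(expr[, idx, drop = FALSE],
                       meta[idx, , drop = FALSE], trend)
      med[b, colnames(a)] <- apply(a, 2L, stats::median, na.rm = TRUE)
    }
  })
  med
}

#' Compare variability between gene groups
#'
#' Per-group per-stage median of a metric plus, per stage, a two-sided
#' Wilcoxon rank-sum test of each group against its complement in the gene
#' universe (BH-corrected across stage x group tests). A group equal to
#' the whole universe is reported without a test.
#'
#' @param vtab a \code{\link{variability_table}} or metric matrix.
#' @param groups named list of gene-id character vectors.
#' @param metric metric name, as in \code{\link{stage_summary}}.
#' @return List: \code{medians} (group x stage data.frame), \code{tests}
#'   (group, stage, statistic, p, p_bh).
#' @export
group_compare <- function(vtab, groups, metric = "adjusted_sd") {
  m <- get_metric(vtab, metric)
  universe <- rownames(m)
  medians <- list(); tests <- list()
  for (g in names(groups)) {
    sel <- intersect(groups[[g]], universe)
    if (!length(sel)) {
      stop("group '", g, "' has empty intersection with gene universe",
           call. = FALSE)
    }
    medians[[g]] <- data.frame(
      group = g, stage = colnames(m),
      median = apply(m[sel, , drop = FALSE], 2L, stats::median,
                     na.rm = TRUE),
      n_genes = length(sel), row.names = NULL)
    comp <- base::setdiff(universe, sel)
    if (!length(comp)) {
      message("group '", g, "' equals the gene universe; test skipped")
      next
    }
    for (j in seq_len(ncol(m))) {
      x <- m[sel, j]; y <- m[comp, j]
      wt <- suppressWarnings(
        stats::wilcox.test(x[is.finite(x)], y[is.finite(y)],
                           exact = FALSE))
      tests[[paste(g, j)]] <- data.frame(
        group = g, stage = colnames(m)[j],
        statistic = unname(wt$statistic), p = wt$p.value)
    }
  }
  tests <- if (length(tests)) do.call(rbind, c(tests,
                                               make.row.names = FALSE))
           else data.frame()
  if (nrow(tests)) tests$p_bh <- stats::p.adjust(tests$p, method = "BH")
  list(medians = do.call(rbind, c(medians, make.row.names = FALSE)),
       tests = tests)
}

#' Genes following the global hourglass variability profile
#'
#' Correlates each gene's across-stage adjusted-SD profile (Pearson) with
#' the across-gene median profile and returns the top fraction. Genes with
#' constant or incomplete profiles are excluded with a note; ties at the
#' cutoff are broken by gene id for determinism.
#'
#' @param vtab a \code{\link{variability_table}} or adjusted-SD matrix.
#' @param top_frac fraction of eligible genes kept.
#' @return Character vector of gene ids (length
#'   \code{floor(top_frac * n_eligible)}), with the per-gene correlations
#'   attached as attribute \code{cor}.
#' @export
hourglass_genes <- function(vtab, top_frac = 0.1) {
  m <- get_metric(vtab, "adjusted_sd")
  complete <- rowSums(!is.finite(m)) == 0L
  sds <- apply(m, 1L, stats::sd)
  ok <- complete & sds > 0
  if (!all(ok)) {
    message(sum(!ok), " gene(s) with constant/incomplete profiles",
            " excluded from hourglass detection")
  }
  m <- m[ok, , drop = FALSE]
  if (nrow(m) < 10L) stop("need >= 10 complete profiles", call. = FALSE)
  med_profile <- apply(m, 2L, stats::median)
  cors <- apply(m, 1L, function(x) stats::cor(x, med_profile))
  k <- floor(top_frac * length(cors))
  ord <- order(-cors, rownames(m))
  sel <- rownames(m)[ord][seq_len(k)]
  structure(sel, cor = cors)
}
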