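#' One-hot artificial stage-expression profiles
#'
#' One template per stage: 1 at the focal stage, 0 elsewhere.
#'
#' @param n_stages number of stages (>= 2).
#' @param labels optional stage labels (default E1..En).
#' @return stages x stages numeric matrix; row s is the template for
#'   stage s.
#' @export
make_profiles <- function(n_stages, labels = NULL) {
  stopifnot(n_stages >= 2L)
  if (is.null(labels)) labels <- stage_labels(n_stages)
  m <- diag(1, n_stages)
  dimnames(m) <- list(labels, labels)
  m
}

#' Stage-specifically expressed genes by template correlation
#'
#' Computes each gene's per-stage mean expression vector, correlates it
#' (Pearson) with every one-hot stage template, and keeps, per template,
#' the \code{floor(top_frac * n_eligible)} genes with the highest
#' correlation (ties broken by gene id). Genes with a constant mean profile
#' have undefined correlations and are excluded with a note. A gene may
#' appear in more than one set; the overlap is reported, not resolved.
#'
#' @param expr genes x samples expression matrix.
#' @param meta sample metadata aligned to columns (\code{stage}).
#' @param profiles template matrix from \code{\link{make_profiles}};
#'   built from the stages present when NULL.
#' @param top_frac fraction of eligible genes kept per stage.
#' @return Named list (one character vector of gene ids per stage) with
#'   attributes \code{correlations} (genes x stages matrix) and
#'   \code{overlap} (count of genes in more than one set).
#' @export
stage_specific_genes <- function(expr, meta, profiles = NULL,
                                 top_frac = 0.1) {
  mom <- stage_moments(expr, meta)
  sm <- mom$mean
  if (is.null(profiles)) {
    profiles <- make_profiles(ncol(sm), colnames(sm))
  }
  stopifnot(ncol(profiles) == ncol(sm))
  eligible <- apply(sm, 1L, stats::sd) > 0
  if (!all(eligible)) {
    message(sum(!eligible), " constant-profile gene(s) excluded from",
            " stage-specific detection")
  }
  sm <- sm[eligible, , drop = FALSE]
  cors <- stats::cor(t(sm), t(profiles))   # genes x stages
  k <- floor(top_frac * nrow(sm))
  sets <- lapply(colnames(cors), function(st) {
    ord <- order(-cors[, st], rownames(sm))
    rownames(sm)[ord][seq_len(k)]
  })
  names(sets) <- colnames(cors)
  n_in <- table(unlist(sets))
  structure(sets, correlations = cors,
            overlap = sum(n_in > 1L))
}
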