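#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{code} with the global RNG seeded at \code{seed}
#' (Mersenne-Twister) and restores the previous RNG state afterwards, so
#' seeded generators do not disturb a caller's random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

#' Derive a child seed from a base seed and a stream label
#'
#' Stable fan-out of one pipeline seed into per-stage seeds: adding a new
#' stream label never shifts the seeds of existing streams. The hash is a
#' small polynomial over the label's UTF-8 bytes, kept below 2^31.
#'
#' @param seed base integer seed.
#' @param label character stream name.
#' @return Integer seed.
#' @export
child_seed <- function(seed, label) {
  stopifnot(length(label) == 1L, is.character(label))
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1000003
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% 2147483647)
}

# population SD (divisor n) along rows of a matrix
row_sd_pop <- function(x) {
  m <- rowMeans(x)
  sqrt(rowMeans((x - m)^2))
}

#' All pairwise two-sided Wilcoxon rank-sum tests with BH correction
#'
#' @param values named list, one numeric vector per group.
#' @return data.frame with columns \code{group1}, \code{group2},
#'   \code{statistic}, \code{p}, \code{p_bh}.
#' @keywords internal
pairwise_wilcox <- function(values) {
  groups <- names(values)
  if (length(groups) < 2L) {
    return(data.frame(group1 = character(), group2 = character(),
                      statistic = numeric(), p = numeric(),
                      p_bh = numeric()))
  }
  pairs <- utils::combn(groups, 2L)
  res <- apply(pairs, 2L, function(pr) {
    x <- values[[pr[1L]]]
    y <- values[[pr[2L]]]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    p <- wt$p.value
    if (is.nan(p)) p <- 1  # degenerate case: identical constant groups
    c(statistic = unname(wt$statistic), p = p)
  })
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    statistic = res["statistic", ], p = res["p", ],
                    row.names = NULL)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

# rank with average ties, NA kept
rank_avg <- function(x) rank(x, ties.method = "average", na.last = "keep")
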