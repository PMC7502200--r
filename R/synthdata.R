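#' Configuration for the synthetic single-embryo experiment generator
#'
#' Bundles every parameter of the synthetic data generator. The defaults
#' emulate a single-embryo 3'-end RNA-seq experiment over fly embryogenesis:
#' 8 ordered developmental stages (E1..E8), 18 isogenic embryos per stage,
#' 4 sequencing libraries (batches), negative-binomial counts with a
#' per-embryo log-normal biological factor whose log-SD is
#' \code{sigma_g * k_s} — a gene-specific noise scale times a stage noise
#' multiplier. The default multipliers are hourglass-shaped with the minimum
#' at stage 3, the phylotypic-like stage.
#'
#' @param n_genes number of genes.
#' @param n_stages number of ordered developmental stages.
#' @param embryos_per_stage integer, recycled to length \code{n_stages}:
#'   embryos collected per stage.
#' @param n_batches number of library batches.
#' @param stage_noise_multipliers positive vector \code{k_s} of length
#'   \code{n_stages}; scales every gene's biological noise at stage s.
#' @param unfertilized_fraction probability in [0,1) that a collected sample
#'   is an unfertilized (developmentally arrested) egg.
#' @param maternal_fraction fraction of genes flagged maternal (deposited in
#'   the egg, declining after stage 1).
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2); 0 gives the Poisson limit. Models
#'   residual technical overdispersion of library preparation only —
#'   embryo-to-embryo biology is carried by the log-normal factor.
#' @param library_size_log_mean,library_size_log_sd log-normal parameters of
#'   per-sample sequencing depth.
#' @param batch_effect_sd log-SD of the multiplicative per-gene batch factor.
#' @param coupling_signal_noise target Spearman correlation in [-1,0] between
#'   promoter histone level and the gene noise scale \code{sigma_g}.
#' @param coupling_signal_cons target Spearman correlation in [-1,0] between
#'   promoter conservation and \code{sigma_g}.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param mu_log_mean,mu_log_sd log-normal parameters of baseline gene
#'   expression levels (relative abundances).
#' @param sigma_log_mean,sigma_log_sd log-normal parameters of the per-gene
#'   noise scale \code{sigma_g}.
#' @param sigma_mean_slope exponent coupling the noise scale to baseline
#'   expression (\code{sigma_g} is multiplied by
#'   \code{(mu_g / median(mu))^sigma_mean_slope}); the negative default
#'   encodes the widely observed excess noise of lowly expressed genes.
#' @param arrested_divergence_sd per-gene log-SD of the arrested profile's
#'   divergence from the stage-1 fertilized profile (unfertilized eggs stall
#'   after meiosis and drift away from every developmental stage).
#' @param stage_effect_sd SD of the per-gene smooth stage-trajectory
#'   amplitude on the natural-log scale; controls how stage-patterned
#'   expression is.
#' @param essential_fraction,hub_fraction,meiosis_fraction fractions of genes
#'   flagged essential / network hub / meiosis-related.
#' @param essential_noise_factor,hub_noise_factor multiplier applied to
#'   \code{sigma_g} of flagged genes (values < 1 encode the lower
#'   variability of essential and hub genes).
#' @param gene_length_range,gene_gap_range integer ranges (bp) for gene
#'   lengths and intergenic gaps in the synthetic genome.
#' @param marks histone mark names for which signal tracks are generated.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, embryos_per_stage = 6, seed = 7)
#' sim <- simulate_counts(cfg)
#' dim(sim$counts)
sim_config <- function(n_genes = 5000L,
                       n_stages = 8L,
                       embryos_per_stage = 18L,
                       n_batches = 4L,
                       stage_noise_multipliers =
                         c(1.6, 1.3, 1.0, 1.05, 1.2, 1.1, 1.3, 1.5),
                       unfertilized_fraction = 0,
                       maternal_fraction = 0.5,
                       nb_dispersion = 0.01,
                       library_size_log_mean = log(1e6),
                       library_size_log_sd = 0.25,
                       batch_effect_sd = 0.1,
                       coupling_signal_noise = -0.4,
                       coupling_signal_cons = -0.3,
                       seed = 1L,
                       mu_log_mean = log(100),
                       mu_log_sd = 1.5,
                       sigma_log_mean = log(0.35),
                       sigma_log_sd = 0.5,
                       sigma_mean_slope = -0.27,
                       arrested_divergence_sd = 1.2,
                       stage_effect_sd = 0.7,
                       essential_fraction = 0.15,
                       hub_fraction = 0.1,
                       meiosis_fraction = 0.02,
                       essential_noise_factor = 0.7,
                       hub_noise_factor = 0.7,
                       gene_length_range = c(2000L, 8000L),
                       gene_gap_range = c(4000L, 12000L),
                       marks = c("H3K4me3", "H3K9ac", "H3K27ac")) {
  cfg <- list(n_genes = as.integer(n_genes), n_stages = as.integer(n_stages),
              embryos_per_stage =
                rep_len(as.integer(embryos_per_stage), as.integer(n_stages)),
              n_batches = as.integer(n_batches),
              stage_noise_multipliers = as.numeric(stage_noise_multipliers),
              unfertilized_fraction = unfertilized_fraction,
              maternal_fraction = maternal_fraction,
              nb_dispersion = nb_dispersion,
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              batch_effect_sd = batch_effect_sd,
              coupling_signal_noise = coupling_signal_noise,
              coupling_signal_cons = coupling_signal_cons,
              seed = as.integer(seed),
              mu_log_mean = mu_log_mean, mu_log_sd = mu_log_sd,
              sigma_log_mean = sigma_log_mean, sigma_log_sd = sigma_log_sd,
              sigma_mean_slope = sigma_mean_slope,
              arrested_divergence_sd = arrested_divergence_sd,
              stage_effect_sd = stage_effect_sd,
              essential_fraction = essential_fraction,
              hub_fraction = hub_fraction,
              meiosis_fraction = meiosis_fraction,
              essential_noise_factor = essential_noise_factor,
              hub_noise_factor = hub_noise_factor,
              gene_length_range = as.integer(gene_length_range),
              gene_gap_range = as.integer(gene_gap_range),
              marks = as.character(marks))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_genes) || cfg$n_genes < 1L) {
    stop("n_genes must be a positive integer", call. = FALSE)
  }
  if (is.na(cfg$n_stages) || cfg$n_stages < 1L) {
    stop("n_stages must be a positive integer", call. = FALSE)
  }
  if (any(is.na(cfg$embryos_per_stage)) || any(cfg$embryos_per_stage < 2L)) {
    stop("embryos_per_stage must all be >= 2", call. = FALSE)
  }
  if (cfg$n_batches < 1L) stop("n_batches must be >= 1", call. = FALSE)
  k <- cfg$stage_noise_multipliers
  if (length(k) != cfg$n_stages || any(!is.finite(k)) || any(k <= 0)) {
    stop("stage_noise_multipliers must be ", cfg$n_stages,
         " positive reals", call. = FALSE)
  }
  fr <- c(cfg$unfertilized_fraction, cfg$maternal_fraction)
  if (any(fr < 0) || any(fr >= 1)) {
    stop("fractions must lie in [0, 1)", call. = FALSE)
  }
  for (nm in c("coupling_signal_noise", "coupling_signal_cons")) {
    v <- cfg[[nm]]
    if (!is.finite(v) || v < -1 || v > 0) {
      stop(nm, " must lie in [-1, 0]", call. = FALSE)
    }
  }
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (cfg$batch_effect_sd < 0) {
    stop("batch_effect_sd must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
#' @method print sim_config
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_stages, "stages x",
      paste(range(x$embryos_per_stage), collapse = "-"),
      "embryos,", x$n_batches, "batches, seed", x$seed, "\n")
  cat("  k_s =", paste(format(x$stage_noise_multipliers), collapse = " "),
      "\n")
  invisible(x)
}

stage_labels <- function(n_stages) sprintf("E%d", seq_len(n_stages))

# Gene-level latent draws shared by counts and genome simulation.
draw_gene_latents <- function(cfg) {
  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  mu <- rlnorm(n, cfg$mu_log_mean, cfg$mu_log_sd)
  sigma <- rlnorm(n, cfg$sigma_log_mean, cfg$sigma_log_sd) *
    (mu / stats::median(mu))^cfg$sigma_mean_slope
  essential <- runif(n) < cfg$essential_fraction
  hub <- runif(n) < cfg$hub_fraction
  maternal <- runif(n) < cfg$maternal_fraction
  meiosis <- runif(n) < cfg$meiosis_fraction
  sigma[essential] <- sigma[essential] * cfg$essential_noise_factor
  sigma[hub] <- sigma[hub] * cfg$hub_noise_factor

  # smooth per-gene stage trajectories: linear drift + one Gaussian bump,
  # plus an exponential maternal-decay component for maternal genes
  s <- seq_len(cfg$n_stages)
  s_std <- (s - mean(s)) / max(1, (cfg$n_stages - 1) / 2)
  slope <- rnorm(n, 0, 0.4 * cfg$stage_effect_sd)
  amp <- rnorm(n, 0, cfg$stage_effect_sd)
  centre <- runif(n, 1, cfg$n_stages)
  wdt <- runif(n, 0.8, 2)
  mat_amp <- ifelse(maternal, abs(rnorm(n, 1, 0.5)), 0)
  mat_tau <- runif(n, 1, 2.5)
  f <- matrix(0, n, cfg$n_stages)
  for (j in s) {
    f[, j] <- slope * s_std[j] +
      amp * exp(-((j - centre)^2) / (2 * wdt^2)) +
      mat_amp * exp(-(j - 1) / mat_tau)
  }
  f <- f - rowMeans(f)
  mu_stage <- mu * exp(f)
  dimnames(mu_stage) <- list(gene_id, stage_labels(cfg$n_stages))

  list(gene_id = gene_id, mu = mu, sigma = sigma, essential = essential,
       hub = hub, maternal = maternal, meiosis = meiosis,
       mu_stage = mu_stage)
}

#' Simulate a single-embryo count matrix with known ground truth
#'
#' Draws an integer count matrix emulating replicate single-embryo 3'-end
#' transcriptomes over ordered developmental stages. For a fertilized embryo
#' j at stage s, gene g receives a negative-binomial draw with mean
#' \code{L_j * p_gjs}, where \code{p_gjs} is the normalized expression
#' fraction obtained from the stage mean \code{mu_gs} perturbed by a
#' per-embryo log-normal biological factor with log-SD
#' \code{sigma_g * k_s} and a multiplicative per-gene batch factor.
#' Unfertilized samples draw from one stage-independent arrested profile
#' (a maternal, meiosis-enriched stage-1-like profile) regardless of their
#' nominal collection stage. Every latent quantity is recorded in the
#' returned truth table.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with elements \code{counts} (genes x samples integer
#'   matrix), \code{meta} (data.frame: \code{sample_id}, \code{stage}
#'   ordered factor, \code{batch}), and \code{truth} (class
#'   \code{sim_truth}: gene table, per-stage mean matrix, arrested profile,
#'   sample table with fertilized flags and library sizes, the \code{k_s}
#'   vector, and the configuration).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    g <- draw_gene_latents(config)
    n <- config$n_genes
    n_samp <- sum(config$embryos_per_stage)
    stg <- rep(stage_labels(config$n_stages),
               times = config$embryos_per_stage)
    sample_id <- sprintf("s%03d_%s", seq_len(n_samp), stg)
    batch <- sample(rep_len(seq_len(config$n_batches), n_samp))
    lib <- rlnorm(n_samp, config$library_size_log_mean,
                  config$library_size_log_sd)
    fertilized <- rbinom(n_samp, 1L, 1 - config$unfertilized_fraction) == 1L

    # per-gene multiplicative batch factors
    bf <- matrix(exp(rnorm(n * config$n_batches, 0, config$batch_effect_sd)),
                 n, config$n_batches)
    if (config$batch_effect_sd == 0) bf[] <- 1

    # stage-independent arrested profile: stage-1-like but transcriptionally
    # diverged (meiosis completed, no zygotic program), meiosis genes up
    arrested <- g$mu_stage[, 1L] *
      exp(rnorm(n, 0, config$arrested_divergence_sd)) *
      ifelse(g$meiosis, 4, 1)

    k <- config$stage_noise_multipliers
    stage_idx <- rep(seq_len(config$n_stages),
                     times = config$embryos_per_stage)
    counts <- matrix(0L, n, n_samp,
                     dimnames = list(g$gene_id, sample_id))
    for (j in seq_len(n_samp)) {
      if (fertilized[j]) {
        base <- g$mu_stage[, stage_idx[j]]
        noise_sd <- g$sigma * k[stage_idx[j]]
      } else {
        base <- arrested
        noise_sd <- g$sigma
      }
      w <- base * exp(rnorm(n, 0, noise_sd)) * bf[, batch[j]]
      lam <- lib[j] * w / sum(w)
      counts[, j] <- as.integer(if (config$nb_dispersion > 0) {
        rnbinom(n, mu = lam, size = 1 / config$nb_dispersion)
      } else {
        rpois(n, lam)
      })
    }

    meta <- data.frame(
      sample_id = sample_id,
      stage = factor(stg, levels = stage_labels(config$n_stages),
                     ordered = TRUE),
      batch = factor(batch),
      stringsAsFactors = FALSE)
    genes <- data.frame(
      gene_id = g$gene_id, mu = g$mu, sigma = g$sigma,
      essential = g$essential, hub = g$hub, maternal = g$maternal,
      meiosis = g$meiosis, stringsAsFactors = FALSE)
    samples <- cbind(meta,
                     data.frame(fertilized = fertilized,
                                library_size = lib))
    truth <- structure(
      list(genes = genes, mu_stage = g$mu_stage,
           arrested_profile = setNames(arrested, g$gene_id),
           samples = samples, k = k, config = config),
      class = "sim_truth")
    list(counts = counts, meta = meta, truth = truth)
  })
}

#' @export
#' @method print sim_truth
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$genes), "genes,", nrow(x$samples), "samples (",
      sum(x$samples$fertilized), "fertilized )\n")
  invisible(x)
}

# Gaussian-copula companion: draw y with target Spearman correlation rho_s
# against x, returning normal scores to be mapped through any monotone
# quantile function. Pearson on normal scores = 2*sin(pi*rho_s/6).
copula_scores <- function(x, rho_s) {
  n <- length(x)
  zx <- qnorm((rank(x, ties.method = "average") - 0.5) / n)
  rho_p <- 2 * sin(pi * rho_s / 6)
  rho_p * zx + sqrt(max(0, 1 - rho_p^2)) * rnorm(n)
}

#' Simulate genome fixtures coupled to an expression-noise truth table
#'
#' Builds a synthetic genome around the genes of a \code{\link{sim_truth}}:
#' gene models laid end-to-end on six fly-like chromosome arms (one
#' representative TSS per gene), a per-base promoter conservation track, one
#' 35-bp-window histone signal track per mark per stage, and a promoter
#' shape index table. Promoter conservation and histone level are coupled
#' to the gene noise scale \code{sigma_g} through a Gaussian copula so that
#' their Spearman correlations match \code{coupling_signal_cons} and
#' \code{coupling_signal_noise}. Histone level is modulated across stages
#' inversely to the stage noise multipliers (the quietest stage gets the
#' strongest promoter signal). The drawn per-gene feature values are
#' appended to \code{truth$genes} in the returned bundle.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth the \code{sim_truth} from \code{\link{simulate_counts}}.
#' @param marks subset of \code{config$marks} to generate tracks for.
#' @param stages integer indices of stages to generate tracks for
#'   (default all).
#' @return An object of class \code{genome_bundle}: \code{models} (GRanges
#'   with \code{gene_id}), \code{conservation} (per-base RleList, NA where
#'   uncovered), \code{tracks} (nested list \code{[[mark]][[stage]]} of
#'   GRanges with \code{score}), \code{shape_index} (named numeric; lower =
#'   broader promoter), \code{chrom_lengths}, \code{truth} (the input truth
#'   with feature columns added).
#' @export
simulate_genome <- function(config, truth, marks = config$marks,
                            stages = seq_len(config$n_stages)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  validate_sim_config(unclass(config))
  with_seed(child_seed(config$seed, "genome"), {
    genes <- truth$genes
    n <- nrow(genes)

    chroms <- c("chr2L", "chr2R", "chr3L", "chr3R", "chrX", "chr4")
    chrom_p <- c(0.2, 0.2, 0.2, 0.2, 0.15, 0.05)
    chrom <- sample(chroms, n, replace = TRUE, prob = chrom_p)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    glen <- round(runif(n, config$gene_length_range[1L],
                        config$gene_length_range[2L]))
    gap <- round(runif(n, config$gene_gap_range[1L],
                       config$gene_gap_range[2L]))

    start <- integer(n)
    chrom_lengths <- setNames(integer(length(chroms)), chroms)
    for (ch in chroms) {
      idx <- which(chrom == ch)
      if (!length(idx)) { chrom_lengths[ch] <- 50000L; next }
      st <- 10000L + cumsum(c(0L, head(glen[idx] + gap[idx], -1L)))
      start[idx] <- st
      chrom_lengths[ch] <- as.integer(st[length(st)] +
                                        glen[idx[length(idx)]] + 10000L)
    }
    models <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start, width = glen),
      strand = strand,
      gene_id = genes$gene_id,
      seqlengths = chrom_lengths)
    names(models) <- genes$gene_id

    # copula-coupled per-gene regulatory features
    cons_level <- round(qbeta(pnorm(
      copula_scores(genes$sigma, config$coupling_signal_cons)), 2, 2), 4)
    hist_base <- qlnorm(pnorm(
      copula_scores(genes$sigma, config$coupling_signal_noise)),
      log(5), 0.5)
    # shape index coupled (positively) to histone level: sharp promoters
    # carry more localized signal; lower index = broader promoter
    shape <- round(copula_scores(hist_base, 0.4), 4)
    names(shape) <- genes$gene_id

    k <- config$stage_noise_multipliers
    stage_mod <- (max(k) + min(k)) - k
    stage_mod <- stage_mod / mean(stage_mod)
    hist_level <- outer(hist_base, stage_mod)
    dimnames(hist_level) <- list(genes$gene_id,
                                 stage_labels(config$n_stages))

    tss <- ifelse(strand == "+", start, start + glen - 1L)

    # conservation: covered only around each TSS (+/- 2500 bp); inner
    # +/- 500 bp at the gene's conservation level, flanks at background 0.1
    conservation <- make_conservation_rle(chrom, tss, cons_level,
                                          chrom_lengths)

    mark_scale <- setNames(rep_len(c(1, 0.8, 1.2), length(config$marks)),
                           config$marks)
    tracks <- list()
    for (mk in marks) {
      tracks[[mk]] <- list()
      for (si in stages) {
        lab <- stage_labels(config$n_stages)[si]
        tracks[[mk]][[lab]] <- make_signal_track(
          chrom_lengths, chrom, tss,
          hist_level[, si] * mark_scale[[mk]])
      }
    }

    genes$phastcons <- cons_level
    genes$histone_base <- hist_base
    genes$shape_index <- as.numeric(shape)
    truth$genes <- genes
    truth$histone_level <- hist_level

    structure(list(models = models, conservation = conservation,
                   tracks = tracks, shape_index = shape,
                   chrom_lengths = chrom_lengths, truth = truth),
              class = "genome_bundle")
  })
}

make_conservation_rle <- function(chrom, tss, level, chrom_lengths) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    r <- S4Vectors::Rle(NA_real_, len)
    idx <- which(chrom == ch)
    for (i in idx) {
      lo <- max(1L, tss[i] - 2500L); hi <- min(len, tss[i] + 2500L)
      r[lo:hi] <- 0.1
    }
    for (i in idx) {
      lo <- max(1L, tss[i] - 500L); hi <- min(len, tss[i] + 500L)
      r[lo:hi] <- level[i]
    }
    out[[ch]] <- r
  }
  methods::as(out, "RleList")
}

# 35-bp windows tiling each chromosome; exponential background, promoter
# windows (TSS +/- 2 kb) at the gene's stage-specific histone level with
# multiplicative noise; scores rounded to 3 decimals (tag-density style)
make_signal_track <- function(chrom_lengths, chrom, tss, level,
                              window = 35L, half_width = 2000L) {
  grl <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(1L, len, by = window)
    ends <- pmin(starts + window - 1L, len)
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(starts, ends))
    sc <- stats::rexp(length(gr), rate = 2)
    idx <- which(chrom == ch)
    if (length(idx)) {
      prom <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(pmax(1L, tss[idx] - half_width),
                             pmin(len, tss[idx] + half_width - 1L)))
      hits <- GenomicRanges::findOverlaps(gr, prom)
      qi <- S4Vectors::queryHits(hits)
      lv <- level[idx][S4Vectors::subjectHits(hits)]
      sc[qi] <- lv * exp(rnorm(length(qi), 0, 0.2))
    }
    gr$score <- round(pmax(sc, 0), 3)
    gr
  })
  gr <- suppressWarnings(do.call(c, grl))
  GenomeInfoDb::seqlengths(gr) <- chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' @export
#' @method print genome_bundle
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle:", length(x$models), "genes on",
      length(x$chrom_lengths), "chromosomes;",
      length(x$tracks), "mark(s) x",
      if (length(x$tracks)) length(x$tracks[[1L]]) else 0, "stage track(s)\n")
  invisible(x)
}
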