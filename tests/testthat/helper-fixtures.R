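# lazily built, cached fixtures shared across test files
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default-condition (hourglass) simulation, preprocessed to expression
hourglass_fixture <- function() {
  fixture("hourglass", function() {
    cfg <- sim_config(n_genes = 2000, embryos_per_stage = 12, seed = 101)
    sim <- simulate_counts(cfg)
    keep_s <- qc_filter(sim$counts, min_genes = 500)
    keep_g <- filter_genes(sim$counts[, keep_s])
    meta <- sim$meta[match(keep_s, sim$meta$sample_id), , drop = FALSE]
    expr <- suppressMessages(correct_batch(
      normalize_counts(sim$counts[keep_g, keep_s]), meta))
    vtab <- suppressMessages(variability_table(expr, meta))
    list(cfg = cfg, sim = sim, expr = expr, meta = meta, vtab = vtab)
  })
}

# small genome bundle coupled to a small counts truth
genome_fixture <- function() {
  fixture("genome", function() {
    cfg <- sim_config(n_genes = 300, embryos_per_stage = 6, seed = 7,
                      gene_length_range = c(1000L, 3000L),
                      gene_gap_range = c(4000L, 6000L))
    sim <- simulate_counts(cfg)
    bundle <- simulate_genome(cfg, sim$truth, marks = "H3K4me3",
                              stages = 1:3)
    list(cfg = cfg, sim = sim, bundle = bundle)
  })
}

# compact genome for file round-trip tests
small_genome_fixture <- function() {
  fixture("small_genome", function() {
    cfg <- sim_config(n_genes = 40, embryos_per_stage = 4, seed = 17,
                      gene_length_range = c(500L, 1500L),
                      gene_gap_range = c(3000L, 4000L),
                      marks = "H3K4me3")
    sim <- simulate_counts(cfg)
    bundle <- simulate_genome(cfg, sim$truth, marks = "H3K4me3",
                              stages = 1L)
    list(cfg = cfg, sim = sim, bundle = bundle)
  })
}

# deterministic toy count matrix with exact QC boundary cases
qc_toy_counts <- function() {
  n_genes <- 6000L
  mk <- function(n_expressed, total) {
    x <- integer(n_genes)
    x[seq_len(n_expressed - 1L)] <- 1L
    x[n_expressed] <- total - (n_expressed - 1L)
    x
  }
  m <- cbind(
    below_reads = mk(6000L, 299999L),
    at_both = mk(4500L, 300000L),
    good = mk(5000L, 1000000L),
    below_genes = mk(4000L, 500000L))
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  m
}
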