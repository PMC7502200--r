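test_that("QC removes samples strictly below either threshold", {
  counts <- qc_toy_counts()
  keep <- qc_filter(counts)
  expect_identical(as.character(keep), c("at_both", "good"))
  rep <- attr(keep, "report")
  expect_identical(rep$qc_pass, c(FALSE, TRUE, TRUE, FALSE))
  # idempotence
  expect_identical(as.character(qc_filter(counts[, keep])),
                   as.character(keep))
  expect_error(qc_filter(counts, min_reads = 1e9), "all samples removed")
})

test_that("QC applies both rules jointly on a derived toy", {
  n_genes <- 6000L
  mk <- function(n_expressed, total) {
    x <- integer(n_genes)
    x[seq_len(n_expressed - 1L)] <- 1L
    x[n_expressed] <- total - (n_expressed - 1L)
    x
  }
  m <- cbind(s1 = mk(5000L, 1000000L), s2 = mk(5000L, 200000L),
             s3 = mk(4000L, 500000L), s4 = mk(5000L, 100000L))
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  expect_identical(as.character(qc_filter(m)), "s1")
})

test_that("gene filter keeps mean cpm strictly above 1", {
  m <- rbind(kept = c(3L, 0L), at_one = c(1L, 1L), zero = c(0L, 0L),
             filler = c(999996L, 999999L))
  colnames(m) <- c("a", "b")
  expect_identical(colSums(m), c(a = 1e6, b = 1e6))
  keep <- filter_genes(m)
  expect_true("kept" %in% keep)      # mean cpm 1.5
  expect_false("at_one" %in% keep)   # mean cpm exactly 1
  expect_false("zero" %in% keep)
  # idempotence
  expect_identical(filter_genes(m[keep, ]), keep)
  m2 <- m; m2[, 2] <- 0L
  expect_error(filter_genes(m2), "zero total")
})

test_that("quantile normalization equalizes sorted columns exactly", {
  set.seed(4)
  counts <- matrix(rnbinom(300 * 6, mu = 40, size = 2), 300, 6,
                   dimnames = list(sprintf("g%03d", 1:300),
                                   sprintf("s%d", 1:6)))
  e <- normalize_counts(counts)
  srt <- apply(e, 2L, sort)
  expect_identical(srt[, 1], srt[, 2])
  for (j in 2:6) expect_identical(srt[, 1], srt[, j])
})

test_that("normalization is a fixed point for permuted columns", {
  set.seed(5)
  x <- rnbinom(200, mu = 30, size = 3)
  counts <- cbind(a = x, b = sample(x))
  rownames(counts) <- sprintf("g%03d", 1:200)
  e <- normalize_counts(counts)
  expect_equal(unname(sort(e[, "a"])), unname(sort(e[, "b"])))
  expect_error(normalize_counts(counts[, 1, drop = FALSE]), "2 samples")
})

test_that("normalization matches a hand-rolled reference", {
  counts <- matrix(c(10L, 200L, 30L, 5L, 300L, 80L, 22L, 40L, 60L), 3, 3,
                   dimnames = list(c("g1", "g2", "g3"),
                                   c("s1", "s2", "s3")))
  lg <- log2(t(t(counts) / colSums(counts)) * 1e6 + 0.5)
  ref <- rowMeans(apply(lg, 2L, sort))
  expected <- apply(lg, 2L, function(x) ref[rank(x, ties.method = "first")])
  dimnames(expected) <- dimnames(counts)
  expect_equal(normalize_counts(counts), expected, tolerance = 1e-12)
  # the averaged-ties variant is the limma convention
  expect_equal(normalize_counts(counts, ties = "average"),
               limma::normalizeQuantiles(lg, ties = TRUE),
               ignore_attr = TRUE)
})

test_that("single-batch correction is a clipped no-op", {
  set.seed(6)
  e <- matrix(abs(rnorm(50 * 6, 5)), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("s%d", 1:6)))
  e[3, 2] <- 0
  meta <- data.frame(sample_id = colnames(e),
                     stage = rep(c("E1", "E2"), each = 3),
                     batch = "b1")
  out <- correct_batch(e, meta)
  expect_identical(out, e)  # no negatives present, zero stays zero
})

test_that("zeros stay zero and negatives are clipped after correction", {
  set.seed(7)
  n <- 80
  e <- matrix(abs(rnorm(n * 8, 4, 2)), n, 8,
              dimnames = list(sprintf("g%02d", 1:n),
                              sprintf("s%d", 1:8)))
  zero_idx <- cbind(sample(n, 15), sample(8, 15, replace = TRUE))
  e[zero_idx] <- 0
  meta <- data.frame(sample_id = colnames(e),
                     stage = rep(c("E1", "E2"), 4),
                     batch = rep(c("b1", "b2"), each = 4))
  out <- correct_batch(e, meta)
  expect_true(all(out >= 0))
  expect_true(all(out[e == 0] == 0))
})

test_that("an additive batch offset is removed", {
  set.seed(8)
  n <- 200
  base <- matrix(rnorm(n * 20, 8, 1), n, 20,
                 dimnames = list(sprintf("g%03d", 1:n),
                                 sprintf("s%02d", 1:20)))
  delta <- rnorm(n, 0, 1.5)
  batch <- rep(c("b1", "b2"), each = 10)
  e <- base
  e[, batch == "b2"] <- e[, batch == "b2"] + delta
  meta <- data.frame(sample_id = colnames(e),
                     stage = rep(rep(c("E1", "E2"), each = 5), 2),
                     batch = batch)
  out <- correct_batch(e, meta)
  gap <- rowMeans(out[, batch == "b1"]) - rowMeans(out[, batch == "b2"])
  expect_lt(max(abs(gap)), 0.8)
  expect_lt(sd(gap), sd(delta) / 5)
})

test_that("stage-mean differences survive protected correction", {
  set.seed(9)
  n <- 150
  stage_shift <- rnorm(n, 0, 1)
  e <- matrix(rnorm(n * 16, 6, 0.5), n, 16,
              dimnames = list(sprintf("g%03d", 1:n),
                              sprintf("s%02d", 1:16)))
  stage <- rep(c("E1", "E2"), each = 8)
  e[, stage == "E2"] <- e[, stage == "E2"] + stage_shift
  meta <- data.frame(sample_id = colnames(e), stage = stage,
                     batch = rep(c("b1", "b2"), 8))
  out <- correct_batch(e, meta, protect_stage = TRUE)
  got <- rowMeans(out[, stage == "E2"]) - rowMeans(out[, stage == "E1"])
  expect_gt(cor(got, stage_shift), 0.95)
})

test_that("1:1 batch-stage confounding errors under protection", {
  e <- matrix(abs(rnorm(40 * 8, 5)), 40, 8,
              dimnames = list(sprintf("g%02d", 1:40),
                              sprintf("s%d", 1:8)))
  meta <- data.frame(sample_id = colnames(e),
                     stage = rep(c("E1", "E2"), each = 4),
                     batch = rep(c("b1", "b2"), each = 4))
  expect_error(correct_batch(e, meta), "confounded")
})

test_that("MDS embeds equal distances as an equilateral triangle", {
  # identity-like columns have all pairwise correlations equal
  e <- diag(5)[, 1:3] + 1
  rownames(e) <- sprintf("g%d", 1:5)
  colnames(e) <- c("a", "b", "c")
  emb <- mds_embed(e)
  d <- dist(emb)
  expect_lt(max(d) - min(d), 1e-8)
})

test_that("a duplicated sample embeds onto its twin", {
  set.seed(10)
  e <- matrix(rnorm(100 * 4, 5), 100, 4,
              dimnames = list(sprintf("g%03d", 1:100),
                              c("a", "b", "c", "a2")))
  e[, "a2"] <- e[, "a"]
  emb <- mds_embed(e)
  expect_lt(sqrt(sum((emb["a", ] - emb["a2", ])^2)), 1e-8)
  e[, "b"] <- 3
  expect_error(mds_embed(e), "constant")
})

test_that("MDS recovers the developmental trajectory order", {
  fx <- hourglass_fixture()
  emb <- mds_embed(fx$expr)
  rho <- cor(as.integer(fx$meta$stage), emb[, 1], method = "spearman")
  expect_gt(abs(rho), 0.9)
})

test_that("arrested samples are flagged against the truth table", {
  cfg <- sim_config(n_genes = 1500, embryos_per_stage = 12, seed = 31,
                    unfertilized_fraction = 0.3)
  sim <- simulate_counts(cfg)
  keep_s <- qc_filter(sim$counts, min_genes = 500)
  keep_g <- filter_genes(sim$counts[, keep_s])
  meta <- sim$meta[match(keep_s, sim$meta$sample_id), ]
  expr <- correct_batch(normalize_counts(sim$counts[keep_g, keep_s]), meta)
  ref <- log2(sim$truth$arrested_profile[rownames(expr)] /
                sum(sim$truth$arrested_profile) * 1e6 + 0.5)
  meiosis <- sim$truth$genes$gene_id[sim$truth$genes$meiosis]
  fl <- flag_unfertilized(expr, ref, meiosis)
  truth_arr <- !sim$truth$samples$fertilized[
    match(fl$sample_id, sim$truth$samples$sample_id)]
  expect_gte(mean(fl$arrested == truth_arr), 0.95)
  # arrested samples carry the higher meiosis enrichment score
  expect_gt(mean(fl$meiosis_score[truth_arr]),
            mean(fl$meiosis_score[!truth_arr]))
})

test_that("nothing is flagged when no arrested cluster exists", {
  fx <- hourglass_fixture()
  ref <- log2(fx$sim$truth$arrested_profile[rownames(fx$expr)] /
                sum(fx$sim$truth$arrested_profile) * 1e6 + 0.5)
  fl <- flag_unfertilized(fx$expr, ref)
  expect_false(any(fl$arrested))
  expect_true(all(is.na(fl$meiosis_score)))
  expect_warning(flag_unfertilized(fx$expr, ref,
                                   meiosis_genes = "not_a_gene"),
                 "meiosis")
})

test_that("X/autosome ratios behave under a shifted X", {
  gid <- sprintf("g%02d", 1:40)
  models <- GenomicRanges::GRanges(
    rep(c("chrX", "chr2"), each = 20),
    IRanges::IRanges(seq(1000, by = 5000, length.out = 40), width = 100),
    strand = "+", gene_id = gid)
  set.seed(12)
  e <- matrix(rnorm(40 * 3, 5, 0.1), 40, 3,
              dimnames = list(gid, c("s1", "s2", "s3")))
  r <- x_autosome_ratio(e, models)
  expect_true(all(abs(r - 1) < 0.05))
  e2 <- e
  e2[1:20, "s2"] <- e2[1:20, "s2"] + 1
  r2 <- x_autosome_ratio(e2, models)
  expect_gt(r2[["s2"]], r[["s2"]] + 0.15)
  expect_error(
    x_autosome_ratio(e[1:20, ], models[1:20]), "autosomal")
})
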