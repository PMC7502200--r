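test_that("trend degree selection follows the nested F-test", {
  set.seed(20)
  m <- runif(500, 1, 10)
  # exact linear truth: degree-2 term never significant
  tr1 <- fit_sd_trend(m, 2 + 0.5 * m + rnorm(500, 0, 1e-8))
  expect_identical(tr1$degree, 1L)
  # quadratic truth with small noise
  m2 <- runif(2000, 1, 10)
  s2 <- 1 + 0.3 * m2 - 0.02 * m2^2 + rnorm(2000, 0, 0.02)
  tr2 <- fit_sd_trend(m2, s2)
  expect_identical(tr2$degree, 2L)
  # constant truth: intercept-only retained
  tr0 <- fit_sd_trend(m, rep(3, 500) + rnorm(500, 0, 1e-6))
  expect_identical(tr0$degree, 0L)
  expect_equal(predict(tr0, c(2, 5)), rep(3, 2), tolerance = 1e-4)
  expect_error(fit_sd_trend(1:5, 1:5), ">= 20 genes")
})

test_that("trend predictions used as divisors are floored", {
  set.seed(21)
  m <- runif(100, 0, 10)
  tr <- fit_sd_trend(m, 0.1 * m + rnorm(100, 0, 0.01))
  expect_true(all(predict(tr, c(-50, 0, 5)) >= tr$eps))
  expect_lt(predict(tr, -50, floor = FALSE), 0)
})

test_that("adjusted SD equals the hand-computed stage/trend ratio", {
  set.seed(22)
  n <- 10
  e <- matrix(rnorm(n * 6, 8, 1), n, 6,
              dimnames = list(sprintf("g%02d", 1:n),
                              sprintf("s%d", 1:6)))
  meta <- data.frame(sample_id = colnames(e),
                     stage = rep(c("E1", "E2"), each = 3))
  # degree-1 trend fitted on a separate larger panel, then applied
  set.seed(23)
  mm <- runif(200, 4, 12)
  tr <- fit_sd_trend(mm, 1 + 0.2 * mm + rnorm(200, 0, 1e-8))
  a <- adjusted_sd(e, meta, tr)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  for (g in 1:n) {
    pred <- 1 + 0.2 * mean(e[g, ])
    expect_equal(a[g, "E1"], pop_sd(e[g, 1:3]) / pred, tolerance = 1e-6)
    expect_equal(a[g, "E2"], pop_sd(e[g, 4:6]) / pred, tolerance = 1e-6)
  }
  # a gene whose stage SD equals its predicted SD has adjusted SD 1
  e2 <- e
  e2[1, ] <- 8 + c(-1, 0, 1, -1, 0, 1) * sqrt(1.5) * (1 + 0.2 * 8)
  a2 <- adjusted_sd(e2, meta, tr)
  expect_equal(unname(a2[1, "E1"]), 1, tolerance = 1e-6)
})

test_that("CV uses the population SD and masks zero-mean stages", {
  e <- rbind(g1 = c(2, 4, 5, 5), g2 = c(3, 3, 7, 7), g3 = c(0, 0, 1, 3))
  colnames(e) <- sprintf("s%d", 1:4)
  meta <- data.frame(sample_id = colnames(e),
                     stage = rep(c("E1", "E2"), each = 2))
  cv <- cv_by_stage(e, meta)
  expect_equal(unname(cv["g1", "E1"]), 1 / 3)  # sd_pop(2,4)=1, mean 3
  expect_equal(unname(cv["g2", "E1"]), 0)      # constant
  expect_true(is.na(cv["g3", "E1"]))           # all-zero stage masked
})

test_that("DM window assignment sends rank 30 of 75 to the lower window", {
  w <- devnoise:::dm_windows(75L, 50L, 25L)
  expect_identical(w$starts, c(1L, 26L))
  expect_identical(w$assign[30L], 1L)   # centres 25 and 50: 5 vs 20 away
  expect_identical(w$assign[37L], 1L)   # 12 vs 13
  expect_identical(w$assign[38L], 2L)   # 13 vs 12
  # tie at equidistant rank goes to the lower window
  w2 <- devnoise:::dm_windows(100L, 50L, 25L)
  centres <- w2$starts + 24L
  tie_rank <- mean(centres[1:2])
  if (tie_rank == round(tie_rank)) {
    expect_identical(w2$assign[as.integer(tie_rank)], 1L)
  }
  # fewer genes than one window: single window over all genes
  w3 <- devnoise:::dm_windows(30L, 50L, 25L)
  expect_identical(w3$assign, rep(1L, 30L))
})

test_that("DM equals an independent brute-force implementation", {
  set.seed(24)
  n <- 200
  e <- matrix(2^rnorm(n * 12, 3, 1), n, 12,
              dimnames = list(sprintf("g%03d", 1:n),
                              sprintf("s%02d", 1:12)))
  meta <- data.frame(sample_id = colnames(e),
                     stage = rep(c("E1", "E2", "E3"), each = 4))
  dm <- distance_to_median(e, meta)

  # brute force, written independently from first principles
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  gmean <- apply(e, 1, mean)
  gcv2 <- (apply(e, 1, pop_sd) / gmean)^2
  ord <- order(gmean)
  starts <- seq(1, n - 50 + 1, by = 25)
  centres <- starts + 24
  meds <- sapply(starts, function(s) {
    median(log10(gcv2[ord][s:(s + 49)]))
  })
  for (g in sample(n, 30)) {
    rk <- which(ord == g)
    win <- which.min(abs(rk - centres))
    for (st in c("E1", "E2", "E3")) {
      cols <- meta$stage == st
      scv2 <- (pop_sd(e[g, cols]) / mean(e[g, cols]))^2
      want <- log10(scv2) - meds[win]
      expect_equal(dm[rownames(e)[g], st], want, tolerance = 1e-10)
    }
  }
})

test_that("genes with zero global CV are dropped from DM", {
  set.seed(25)
  e <- matrix(2^rnorm(60 * 4, 3, 1), 60, 4,
              dimnames = list(sprintf("g%02d", 1:60),
                              sprintf("s%d", 1:4)))
  e[7, ] <- 5
  meta <- data.frame(sample_id = colnames(e),
                     stage = rep(c("E1", "E2"), each = 2))
  expect_message(dm <- distance_to_median(e, meta), "excluded")
  expect_false("g07" %in% rownames(dm))
})

test_that("stage summary medians and tests behave on two shifted stages", {
  set.seed(26)
  m <- cbind(E1 = rnorm(300, 1), E2 = rnorm(300, 1.4))
  rownames(m) <- sprintf("g%03d", 1:300)
  ss <- stage_summary(m)
  expect_identical(ss$tests$p, ss$tests$p_bh)  # single pair
  expect_lt(ss$tests$p, 0.01)
  expect_error(stage_summary(m[, 1, drop = FALSE]), "2 stages")
  expect_error(stage_summary(hourglass_fixture()$vtab, "nope"),
               "unknown metric")
})

test_that("the hourglass fixture recovers the stage-noise rank order", {
  fx <- hourglass_fixture()
  ss <- stage_summary(fx$vtab, "adjusted_sd")
  expect_identical(ss$medians$stage[which.min(ss$medians$median)], "E3")
  rho <- cor(ss$medians$median, fx$cfg$stage_noise_multipliers,
             method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("bootstrap medians separate stages with distinct noise", {
  fx <- hourglass_fixture()
  bt <- bootstrap_stage_medians(fx$expr, fx$meta, fx$vtab$trend,
                                n_boot = 100, seed = 5)
  expect_identical(dim(bt$medians), c(100L, 8L))
  expect_gt(mean(bt$medians[, "E3"] < bt$medians[, "E1"]), 0.95)
  expect_error(bootstrap_stage_medians(fx$expr, fx$meta, n = 1),
               ">= 2")
})

test_that("bootstrap medians of identical stages sit at the same level", {
  # the bootstrap Wilcoxon is descriptive, not calibrated: it has power
  # against the realized finite-sample difference between the two stages,
  # so the distributions are compared on location and overlap instead
  set.seed(27)
  for (r in 1:5) {
    e <- matrix(2^rnorm(150 * 16, 3, 1), 150, 16,
                dimnames = list(sprintf("g%03d", 1:150),
                                sprintf("s%02d", 1:16)))
    meta <- data.frame(sample_id = colnames(e),
                       stage = rep(c("E1", "E2"), each = 8))
    tr <- fit_sd_trend(rowMeans(e), devnoise:::row_sd_pop(e))
    bt <- bootstrap_stage_medians(e, meta, tr, n_boot = 60, seed = r)
    gap <- abs(mean(bt$medians[, "E1"]) - mean(bt$medians[, "E2"]))
    lvl <- mean(bt$medians)
    expect_lt(gap, 0.2 * lvl)
    # distributions overlap
    expect_gt(max(bt$medians[, "E1"]), min(bt$medians[, "E2"]))
    expect_gt(max(bt$medians[, "E2"]), min(bt$medians[, "E1"]))
  }
})

test_that("equal-n subsampling is the identity at the full stage size", {
  fx <- hourglass_fixture()
  n_full <- min(table(fx$meta$stage))
  sub <- subsample_equal(fx$expr, fx$meta, fx$vtab$trend,
                         n = n_full, reps = 3, seed = 2)
  full <- apply(adjusted_sd(fx$expr, fx$meta, fx$vtab$trend), 2, median)
  for (r in 1:3) expect_equal(sub[r, ], full, tolerance = 1e-12)
  # zero reps: empty result, no error
  empty <- subsample_equal(fx$expr, fx$meta, fx$vtab$trend, n = 2,
                           reps = 0)
  expect_identical(nrow(empty), 0L)
  expect_error(subsample_equal(fx$expr, fx$meta, n = 10000), "smaller")
})

test_that("equal-n subsampling keeps the stage-3 minimum", {
  fx <- hourglass_fixture()
  sub <- subsample_equal(fx$expr, fx$meta, fx$vtab$trend, n = 8,
                         reps = 50, seed = 3)
  mom <- apply(sub, 2, median)
  expect_identical(names(which.min(mom)), "E3")
})

test_that("low-noise gene groups show lower adjusted SD", {
  cfg <- sim_config(n_genes = 2000, embryos_per_stage = 10, seed = 61,
                    essential_noise_factor = 0.5, batch_effect_sd = 0)
  sim <- simulate_counts(cfg)
  keep_g <- filter_genes(sim$counts)
  expr <- normalize_counts(sim$counts[keep_g, ])
  vtab <- suppressMessages(variability_table(expr, sim$meta))
  ess <- intersect(sim$truth$genes$gene_id[sim$truth$genes$essential],
                   rownames(expr))
  gc <- group_compare(vtab, list(essential = ess))
  other <- apply(vtab$adjusted_sd[setdiff(rownames(expr), ess), ], 2,
                 median)
  expect_true(all(gc$medians$median < other))
  expect_true(all(gc$tests$p < 0.05))
  expect_error(group_compare(vtab, list(bad = "nope")), "empty")
  expect_message(group_compare(vtab, list(all = rownames(expr))),
                 "universe")
})

test_that("stage summary on gene subsets preserves the E3 minimum", {
  fx <- hourglass_fixture()
  # always-expressed subset (positive mean expression at every stage)
  mom <- devnoise:::stage_moments(fx$expr, fx$meta)
  always <- rownames(fx$expr)[apply(mom$mean, 1, min) > 0]
  ss <- stage_summary(fx$vtab, "adjusted_sd", genes = always)
  expect_identical(ss$medians$stage[which.min(ss$medians$median)], "E3")
  # maternal-excluded subset
  mat <- fx$sim$truth$genes$gene_id[fx$sim$truth$genes$maternal]
  ss2 <- stage_summary(fx$vtab, "adjusted_sd",
                       genes = setdiff(rownames(fx$expr), mat))
  expect_identical(ss2$medians$stage[which.min(ss2$medians$median)], "E3")
})

test_that("hourglass gene selection follows the top-fraction rule", {
  set.seed(28)
  prof <- c(1.5, 1.2, 1.0, 1.05, 1.15, 1.1, 1.3, 1.45)
  m <- matrix(rnorm(1000 * 8, 1, 0.3), 1000, 8,
              dimnames = list(sprintf("g%04d", 1:1000),
                              sprintf("E%d", 1:8)))
  m <- sweep(m, 2, prof, "+")
  m["g0001", ] <- apply(m, 2, median)  # exactly the median profile
  hg <- hourglass_genes(m, top_frac = 0.1)
  expect_length(hg, 100L)
  expect_true("g0001" %in% hg)
})

test_that("hourglass ranking matches a brute-force oracle", {
  set.seed(29)
  m <- matrix(rnorm(50 * 8, 1, 0.5), 50, 8,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("E%d", 1:8)))
  hg <- hourglass_genes(m, top_frac = 0.2)
  med <- apply(m, 2, median)
  cors <- apply(m, 1, function(x) cor(x, med))
  oracle <- names(sort(-cors))[1:10]
  expect_setequal(as.character(hg), oracle)
})
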