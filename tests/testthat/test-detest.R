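# closed-form check of the plain replicate-level test, frozen from the
# t-distribution oracle: r = (1.0, 1.2, 0.8) has mean 1, sd 0.2,
# t = 1 / (0.2 / sqrt(3)) = 8.6603, df = 2, p = 2 * pt(-8.6603, 2)
test_that("paired plain t matches the closed-form oracle", {
  pc <- 0.1
  ctl <- c(4, 4, 4)
  r <- c(1.0, 1.2, 0.8)
  inj <- (ctl + pc) * 2^r - pc       # engineered so ratios equal r
  expr <- toy_fpkm(list(gA = c(inj, ctl), gB = rep(2, 6)),
                   c("i1", "i2", "i3", "c1", "c2", "c3"))
  spec <- contrast_spec("regenA", "mid", c("i1", "i2", "i3"),
                        c("c1", "c2", "c3"), paired = TRUE,
                        pseudocount = pc)
  res <- test_contrast(expr, spec, method = "t")
  gA <- res[res$gene_id == "gA", ]
  expect_equal(gA$t, 8.6602540, tolerance = 1e-6)
  expect_equal(gA$p, 0.0130725, tolerance = 1e-4)
  # identical replicate FPKMs in both groups -> log2fc 0, NS
  gB <- res[res$gene_id == "gB", ]
  expect_equal(gB$log2fc, 0)
  expect_equal(gB$status, "NS")
})

test_that("below-threshold genes in both conditions are not tested", {
  expr <- toy_fpkm(list(low = rep(0.1, 6), high = rep(5, 6)),
                   c("i1", "i2", "i3", "c1", "c2", "c3"))
  spec <- contrast_spec("regenA", "mid", c("i1", "i2", "i3"),
                        c("c1", "c2", "c3"), paired = TRUE,
                        min_fpkm = 0.45)
  for (m in c("t", "moderated")) {
    # two-gene matrix: limma's variance-prior estimate degenerates, which
    # is irrelevant to the filtering contract under test
    res <- suppressWarnings(test_contrast(expr, spec, method = m))
    expect_equal(res$status[res$gene_id == "low"], "NOTEST")
    expect_true(is.na(res$p[res$gene_id == "low"]))
  }
  # above threshold on one side only is still tested
  expr2 <- toy_fpkm(list(g = c(2, 2.2, 1.8, 0.1, 0.1, 0.1),
                         g2 = rep(5, 6)),
                    c("i1", "i2", "i3", "c1", "c2", "c3"))
  res2 <- test_contrast(expr2, spec, method = "t")
  expect_false(any(res2$status == "NOTEST"))
})

test_that("benjamini_hochberg matches the step-up oracle", {
  expect_equal(benjamini_hochberg(0.01), 0.01)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(2:200, 1L))^sample(1:3, 1L)
    expect_equal(benjamini_hochberg(p), bh_oracle(p))
  }
  # ties receive identical q; order invariance
  p <- c(0.03, 0.01, 0.03, 0.2)
  q <- benjamini_hochberg(p)
  expect_equal(q[1L], q[3L])
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(benjamini_hochberg(p[perm]), q[perm])
})

test_that("swapping injury and control negates log2fc, keeps p", {
  sim <- simulate_experiment(small_sim_config(seed = 13L, n_genes = 400L))
  fpkm <- compute_fpkm(sim$counts, sim$model)
  spec <- contrasts_from_design(sim$design)[["regenA.mid"]]
  swapped <- contrast_spec(spec$tissue, spec$time_point,
                           spec$control_samples, spec$injury_samples,
                           paired = TRUE)
  for (m in c("t", "moderated")) {
    a <- test_contrast(fpkm, spec, method = m)
    b <- test_contrast(fpkm, swapped, method = m)
    expect_equal(b$log2fc, -a$log2fc, tolerance = 1e-12)
    expect_equal(b$p, a$p, tolerance = 1e-12)
  }
})

test_that("unpaired mode reduces to a two-sample test on log2 FPKM", {
  set.seed(3)
  vals <- lapply(1:30, function(i) round(exp(rnorm(6, 1.5, 0.5)), 3))
  names(vals) <- sprintf("g%02d", 1:30)
  expr <- toy_fpkm(vals, c("i1", "i2", "i3", "c1", "c2", "c3"))
  spec <- contrast_spec("nonregen", "early", c("i1", "i2", "i3"),
                        c("c1", "c2", "c3"), paired = FALSE,
                        min_fpkm = 0.01)
  res <- test_contrast(expr, spec, method = "t")
  # oracle: stats::t.test Welch on log2(fpkm + pc), gene by gene
  for (g in c("g01", "g17", "g30")) {
    y <- log2(unlist(vals[g]) + 0.1)
    tt <- t.test(y[1:3], y[4:6])
    expect_equal(res$p[res$gene_id == g], tt$p.value, tolerance = 1e-10)
  }
})

test_that("significance statuses respect sign and the FDR criterion", {
  sim <- simulate_experiment(small_sim_config(seed = 17L, n_genes = 800L))
  fpkm <- compute_fpkm(sim$counts, sim$model)
  res <- test_contrast(fpkm, contrasts_from_design(sim$design)[["regenA.mid"]])
  up <- res[res$status == "UP", ]
  dn <- res[res$status == "DOWN", ]
  expect_true(all(up$log2fc > 0) && all(up$q <= 0.05))
  expect_true(all(dn$log2fc < 0) && all(dn$q <= 0.05))
  ns <- res[res$status == "NS", ]
  expect_true(all(is.na(ns$q) | ns$q > 0.05 | ns$log2fc == 0))
  # q monotone non-decreasing in the rank order of p (tested genes)
  t_ok <- !is.na(res$p)
  o <- order(res$p[t_ok])
  expect_true(all(diff(res$q[t_ok][o]) >= -1e-12))
})

test_that("null simulation keeps the raw p-value rate near nominal", {
  cfg <- simulation_config(n_genes = 2000L, n_desr = 0L, n_opposing = 0L,
                           temporal_profile = zero_effect_profile(),
                           seed = 23L)
  sim <- simulate_experiment(cfg)
  fpkm <- compute_fpkm(sim$counts, sim$model)
  res <- test_contrast(fpkm, contrasts_from_design(sim$design)[["regenB.mid"]])
  p <- res$p[!is.na(res$p)]
  se <- sqrt(0.05 * 0.95 / length(p))
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * se)
  expect_lte(mean(res$q <= 0.05, na.rm = TRUE), 0.05)
})
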