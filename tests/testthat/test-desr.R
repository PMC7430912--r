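test_that("DESR extraction applies the direction-aware three-way filter", {
  a <- toy_de_result("regenA", "mid", up = c("g1", "g2", "g3"),
                     down = c("d1", "d2"))
  b <- toy_de_result("regenB", "mid", up = c("g2", "g3", "g4"),
                     down = c("d1", "d3"))
  n <- toy_de_result("nonregen", "mid", up = "g3", down = character())
  d <- extract_desr(a, b, n)
  expect_equal(d$up_genes, "g2")           # g3 removed: UP in nonregen
  expect_equal(d$down_genes, "d1")
  expect_equal(d$opposing_genes, character(0))
  expect_equal(d$discordant_genes, character(0))
})

test_that("opposing-direction genes stay DESR and are flagged", {
  a <- toy_de_result("regenA", "mid", up = "g5", down = "g6")
  b <- toy_de_result("regenB", "mid", up = "g5", down = "g6")
  n <- toy_de_result("nonregen", "mid", up = "g6", down = "g5")
  d <- extract_desr(a, b, n)
  expect_true("g5" %in% d$up_genes)
  expect_true("g6" %in% d$down_genes)
  expect_setequal(d$opposing_genes, c("g5", "g6"))
  expect_true(all(d$opposing_genes %in% c(d$up_genes, d$down_genes)))
})

test_that("discordant regenerative genes are reported separately", {
  a <- toy_de_result("regenA", "mid", up = "g7")
  b <- toy_de_result("regenB", "mid", down = "g7")
  n <- toy_de_result("nonregen", "mid")
  d <- extract_desr(a, b, n)
  expect_equal(d$discordant_genes, "g7")
  expect_false("g7" %in% c(d$up_genes, d$down_genes))
})

test_that("empty significant sets give an empty DESR set; NS genes inert", {
  a <- toy_de_result("regenA", "mid", ns = c("x", "y"))
  b <- toy_de_result("regenB", "mid", ns = "x")
  n <- toy_de_result("nonregen", "mid")
  d <- extract_desr(a, b, n)
  expect_length(d$up_genes, 0L)
  expect_length(d$down_genes, 0L)
  # adding NS genes to any input changes nothing
  a2 <- toy_de_result("regenA", "mid", up = "g1", ns = letters)
  b2 <- toy_de_result("regenB", "mid", up = "g1")
  d2 <- extract_desr(a2, b2, n)
  expect_equal(d2$up_genes, "g1")
})

test_that("mismatched time points are a hard error", {
  a <- toy_de_result("regenA", "mid", up = "g1")
  b <- toy_de_result("regenB", "late", up = "g1")
  n <- toy_de_result("nonregen", "mid")
  expect_error(extract_desr(a, b, n), "time points")
})

test_that("overlap regions match a brute-force membership oracle", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:100)
  mk <- function(tissue, n_up, n_down) {
    g <- sample(genes, n_up + n_down)
    toy_de_result(tissue, "early", up = g[seq_len(n_up)],
                  down = g[n_up + seq_len(n_down)])
  }
  a <- mk("regenA", 15, 15); b <- mk("regenB", 20, 20)
  n <- mk("nonregen", 25, 25)
  tab <- tabulate_overlaps(a, b, n)
  oracle <- function(direction) {
    sets <- list(A = a$gene_id[a$status == direction],
                 B = b$gene_id[b$status == direction],
                 N = n$gene_id[n$status == direction])
    sapply(genes, function(g) {
      m <- c(g %in% sets$A, g %in% sets$B, g %in% sets$N)
      paste(c("regenA", "regenB", "nonregen")[m], collapse = "&")
    })
  }
  for (dir in c("UP", "DOWN")) {
    keys <- oracle(dir)
    col <- if (dir == "UP") "up_count" else "down_count"
    for (i in seq_len(nrow(tab)))
      expect_equal(tab[[col]][i],
                   sum(keys == tab$region[i], na.rm = TRUE))
  }
  # region counts sum to the per-direction union totals
  expect_equal(sum(tab$up_count),
               length(unique(c(a$gene_id[a$status == "UP"],
                               b$gene_id[b$status == "UP"],
                               n$gene_id[n$status == "UP"]))))
  # the regenA&regenB-only region equals the DESR sets
  d <- extract_desr(a, b, n)
  expect_equal(tab$up_count[tab$region == "regenA&regenB"],
               length(d$up_genes))
  expect_equal(tab$down_count[tab$region == "regenA&regenB"],
               length(d$down_genes))
})

test_that("degenerate overlap cases: disjoint and identical sets", {
  a <- toy_de_result("regenA", "mid", up = c("a1", "a2"))
  b <- toy_de_result("regenB", "mid", up = c("b1", "b2"))
  n <- toy_de_result("nonregen", "mid", up = c("n1", "n2"))
  tab <- tabulate_overlaps(a, b, n)
  expect_true(all(tab$up_count[grepl("&", tab$region)] == 0L))
  same <- c("s1", "s2", "s3", "s4", "s5")
  tab2 <- tabulate_overlaps(toy_de_result("regenA", "mid", up = same),
                            toy_de_result("regenB", "mid", up = same),
                            toy_de_result("nonregen", "mid", up = same))
  expect_equal(tab2$up_count[tab2$region == "regenA&regenB&nonregen"], 5L)
  expect_equal(sum(tab2$up_count), 5L)
})

test_that("temporal summary counts, percentages, and peaks", {
  mk <- function(tissue, tp, n_up, n_down) {
    g <- sprintf("%s_%s_%03d", tissue, tp, seq_len(n_up + n_down))
    toy_de_result(tissue, tp, up = g[seq_len(n_up)],
                  down = g[n_up + seq_len(n_down)])
  }
  counts <- list(regenA = c(early = 5, mid = 20, late = 8),
                 regenB = c(early = 4, mid = 18, late = 6),
                 nonregen = c(early = 30, mid = 10, late = 2))
  results <- list()
  for (tis in names(counts))
    for (tp in c("early", "mid", "late"))
      results[[paste(tis, tp, sep = ".")]] <-
        mk(tis, tp, counts[[tis]][[tp]], 2L)
  ts <- temporal_summary(results, genome_size = 1000L)
  expect_equal(ts$counts$n_total[ts$counts$tissue == "regenA" &
                                   ts$counts$time_point == "mid"], 22L)
  expect_equal(ts$counts$pct_genome[ts$counts$tissue == "nonregen" &
                                      ts$counts$time_point == "early"],
               3.2)
  pk <- ts$peaks
  expect_equal(pk$peak_time_point[pk$tissue == "regenA"], "mid")
  expect_equal(pk$peak_time_point[pk$tissue == "nonregen"], "early")
  expect_false(any(pk$tie))
  expect_error(temporal_summary(results[-1L]), "regenA.early")
})

test_that("all-NS results yield zero counts and tied peaks", {
  results <- list()
  for (tis in c("regenA", "regenB", "nonregen"))
    for (tp in c("early", "mid", "late"))
      results[[paste(tis, tp, sep = ".")]] <-
        toy_de_result(tis, tp, ns = c("g1", "g2"))
  ts <- temporal_summary(results)
  expect_true(all(ts$counts$n_total == 0L))
  expect_true(all(ts$peaks$tie))
})

test_that("DESR share and compound false-count arithmetic", {
  expect_equal(desr_share(324, 12059), 2.7)
  r <- compound_false_count(0.05, 324)
  expect_equal(r$expected_real, 0.81)
  expect_equal(r$expected_rounded, 1)
  expect_equal(compound_false_count(0.3, 0),
               list(expected_real = 0, expected_rounded = 0))
  expect_equal(compound_false_count(0.1, 200)$expected_real, 2.0)
  expect_equal(compound_false_count(0.1, 200)$expected_rounded, 2)
  expect_error(compound_false_count(1.2, 10), "alpha")
  expect_error(compound_false_count(0, 10), "alpha")
})
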