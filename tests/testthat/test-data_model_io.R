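test_that("gene model parsing links partners and rejects bad tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\tsymbol\thomeolog_tag\tpartner_id\tchrom\texonic_length_bp",
    "g1.L\tg1\tL\tg1.S\tchr1L\t1200",
    "g1.S\tg1\tS\tg1.L\tchr1S\t1100"), path)
  m <- read_gene_model(path)
  expect_s3_class(m, "gene_model")
  expect_equal(nrow(m), 2L)
  expect_equal(m["g1.L", "partner_id"], "g1.S")
  expect_equal(m["g1.S", "partner_id"], "g1.L")

  dup <- data.frame(gene_id = c("a", "a"), symbol = "a",
                    homeolog_tag = "none", partner_id = NA,
                    chrom = "chr1", exonic_length_bp = 10)
  expect_error(gene_model(dup), "duplicate gene_id")

  asym <- data.frame(gene_id = c("a.L", "a.S"), symbol = "a",
                     homeolog_tag = c("L", "S"),
                     partner_id = c("a.S", NA), chrom = "chr1",
                     exonic_length_bp = 10)
  expect_error(gene_model(asym), "asymmetric")

  zero <- data.frame(gene_id = "a", symbol = "a", homeolog_tag = "none",
                     partner_id = NA, chrom = "chr1",
                     exonic_length_bp = 0)
  expect_error(gene_model(zero), "positive integer")
})

test_that("GTF input computes exon-union lengths (1-based inclusive)", {
  skip_if_not_installed("rtracklayer")
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1L", "test", "exon", "1", "100", ".", "+", ".",
          'gene_id "gA.L";', sep = "\t"),
    paste("chr1L", "test", "exon", "51", "200", ".", "+", ".",
          'gene_id "gA.L";', sep = "\t")), path)
  m <- read_gene_model(path)
  # interval-union oracle: [1,100] U [51,200] = [1,200], 200 bases
  ivs <- rbind(c(1, 100), c(51, 200))
  covered <- sort(unique(unlist(apply(ivs, 1, function(r) r[1]:r[2]))))
  expect_equal(m$exonic_length_bp, length(covered))
  expect_equal(m$exonic_length_bp, 200L)
})

test_that("count matrix reading validates against the design", {
  design <- study_design(data.frame(
    sample_id = c("s1", "s2"), tissue = "regenA", condition = "injury",
    time_point = "early", replicate = 1:2, pair_id = NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t10\t0", "g2\t5\t7", "g3\t0\t3"),
             path)
  cm <- read_counts(path, design)
  expect_equal(dim(cm), c(3L, 2L))
  expect_equal(unname(total_aligned(cm)), c(15, 10))  # column sums

  design3 <- study_design(data.frame(
    sample_id = c("s1", "s2", "s3"), tissue = "regenA",
    condition = "injury", time_point = "early", replicate = 1:3,
    pair_id = NA))
  expect_error(read_counts(path, design3), "s3")

  totals <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttotal_aligned", "s1\t100", "s2\t200"), totals)
  cm2 <- read_counts(path, design, totals_path = totals)
  expect_equal(unname(total_aligned(cm2)), c(100, 200))
})

test_that("write then read round-trips counts and DE results exactly", {
  sim <- simulate_experiment(small_sim_config(n_genes = 60L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(sim$counts, path)
  back <- read_counts(path, sim$design)
  expect_equal(unclass(back), unclass(sim$counts),
               ignore_attr = "class")

  fpkm <- compute_fpkm(sim$counts, sim$model)
  spec <- contrasts_from_design(sim$design)[["regenA.mid"]]
  res <- test_contrast(fpkm, spec)
  rpath <- withr::local_tempfile(fileext = ".tsv")
  write_de_result(res, rpath)
  back2 <- read_de_result(rpath)
  expect_equal(back2$log2fc, res$log2fc)
  expect_equal(back2$p, res$p)
  expect_equal(back2$q, res$q)
  expect_equal(back2$status, res$status)
  expect_equal(attr(back2, "tissue"), "regenA")
  expect_equal(attr(back2, "time_point"), "mid")
})

test_that("writers are byte-stable and handle empty DESR sets", {
  res <- toy_de_result("regenA", "mid", up = "g1", down = "g2")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_de_result(res, p1)
  write_de_result(res, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  empty <- extract_desr(toy_de_result("regenA", "mid"),
                        toy_de_result("regenB", "mid"),
                        toy_de_result("nonregen", "mid"))
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_desr_set(empty, ep)
  lines <- readLines(ep)
  expect_length(lines, 1L)  # header only, zero data rows
})

test_that("study design validation enforces pairing invariants", {
  bad_pair <- data.frame(
    sample_id = c("a", "b"), tissue = c("regenA", "regenB"),
    condition = c("injury", "control"), time_point = "early",
    replicate = 1L, pair_id = "p1")
  expect_error(study_design(bad_pair), "pair_id")
  ok <- design_template()
  expect_equal(nrow(ok), 51L)
  grp <- unique(paste(ok$tissue, ok$condition, ok$time_point))
  expect_length(grp, 17L)
})
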