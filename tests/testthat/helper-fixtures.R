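# Shared fixtures, built in code at test time.

# minimal two-pair gene model
toy_model <- function() {
  gene_model(data.frame(
    gene_id = c("g1.L", "g1.S", "g2.L", "g2.S", "g3.L"),
    symbol = c("g1", "g1", "g2", "g2", "g3"),
    homeolog_tag = c("L", "S", "L", "S", "none"),
    partner_id = c("g1.S", "g1.L", "g2.S", "g2.L", NA),
    chrom = c("chr1L", "chr1S", "chr2L", "chr2S", "chr3L"),
    exonic_length_bp = c(1000L, 1000L, 2000L, 1500L, 500L),
    stringsAsFactors = FALSE))
}

# fpkm matrix built directly from given values (one row per gene)
toy_fpkm <- function(values, samples) {
  m <- matrix(unlist(values), nrow = length(values), byrow = TRUE,
              dimnames = list(names(values), samples))
  attr(m, "total_aligned") <- stats::setNames(rep(1e6, ncol(m)), samples)
  class(m) <- c("fpkm_matrix", class(m))
  m
}

# hand-built de_result for set-logic tests
toy_de_result <- function(tissue, time_point, up = character(),
                          down = character(), ns = character(),
                          notest = character()) {
  genes <- c(up, down, ns, notest)
  status <- rep(c("UP", "DOWN", "NS", "NOTEST"),
                c(length(up), length(down), length(ns), length(notest)))
  q <- ifelse(status %in% c("UP", "DOWN"), 0.01,
              ifelse(status == "NS", 0.5, NA))
  lfc <- ifelse(status == "UP", 1, ifelse(status == "DOWN", -1, 0))
  structure(
    data.frame(gene_id = genes,
               mean_fpkm_control = rep(1, length(genes)),
               mean_fpkm_injury = 2^lfc, log2fc = lfc,
               t = rep(NA_real_, length(genes)),
               p = q, q = q, status = status, stringsAsFactors = FALSE),
    tissue = tissue, time_point = time_point, alpha = 0.05,
    class = c("de_result", "data.frame"))
}

# small but non-degenerate simulation configuration; planted set sizes
# scale down with tiny genomes so the expressed pool always suffices
small_sim_config <- function(seed = 1L, n_genes = 1500L,
                             n_desr = min(50L, max(2L, n_genes %/% 30L)),
                             n_opposing = min(20L, n_desr %/% 2L), ...) {
  simulation_config(
    n_genes = n_genes,
    temporal_profile = default_temporal_profile(n_genes),
    n_desr = n_desr, n_opposing = n_opposing,
    seed = seed, ...)
}

zero_effect_profile <- function() {
  matrix(0L, 3, 3, dimnames = list(c("regenA", "regenB", "nonregen"),
                                   c("early", "mid", "late")))
}

# independent Benjamini-Hochberg step-up oracle (kept independent of the
# implementation path, which delegates to stats::p.adjust)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}
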