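# Synthetic allotetraploid RNA-seq experiment generator with planted truth.
#
# All randomness flows from one root seed. Sub-stages draw from derived
# streams: sub_seed(seed, k) = (seed * 48271 + k * 2654435761) mod (2^31 - 1),
# so stages are individually reproducible and independent of call order.

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 2654435761) %%
               2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' The canonical three-tissue study design template
#'
#' Mirrors the study layout: two axon-regenerative tissues (`regenA`, a
#' tadpole spinal-cord-injury hindbrain with age-matched paired controls;
#' `regenB`, a frog optic-nerve-crush eye with contralateral paired
#' controls) sampled at three post-injury time points with paired injury
#' and control replicates, one non-regenerative tissue (`nonregen`, frog
#' spinal-cord-injury hindbrain) with a single unpaired control group
#' shared across the three time points, and optionally a surgically naive
#' group used only for ordination. With defaults this yields 17 conditions
#' and 51 samples.
#'
#' @param replicates biological replicates per condition (default 3).
#' @param include_naive include the naive, PCA-only group (default TRUE).
#' @return a [study_design].
#' @export
design_template <- function(replicates = 3L, include_naive = TRUE) {
  rows <- list()
  add <- function(tissue, condition, tp, rep, pair)
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = paste(tissue, condition,
                        ifelse(is.na(tp), "all", tp), rep, sep = "_"),
      tissue = tissue, condition = condition, time_point = tp,
      replicate = rep, pair_id = pair, stringsAsFactors = FALSE)
  for (tissue in c("regenA", "regenB")) {
    for (tp in TIME_POINTS) {
      for (r in seq_len(replicates)) {
        pair <- paste(tissue, tp, r, sep = "_")
        add(tissue, "injury", tp, r, pair)
        add(tissue, "control", tp, r, pair)
      }
    }
  }
  for (tp in TIME_POINTS)
    for (r in seq_len(replicates))
      add("nonregen", "injury", tp, r, NA_character_)
  for (r in seq_len(replicates))
    add("nonregen", "control", NA_character_, r, NA_character_)
  if (include_naive)
    for (r in seq_len(replicates))
      add("regenB", "naive", NA_character_, r, NA_character_)
  study_design(do.call(rbind, rows))
}

#' Default temporal profile of planted tissue-specific DE genes
#'
#' Number of planted injury-responsive genes per tissue and time point.
#' The regenerative tissues peak at the mid (peak axon outgrowth) phase
#' and the non-regenerative tissue at the early (acute trauma) phase,
#' scaled to the total number of genes.
#'
#' @param n_genes total genes in the simulated genome.
#' @return 3 x 3 integer matrix (tissues x time points).
#' @export
default_temporal_profile <- function(n_genes) {
  frac <- rbind(regenA  = c(early = 0.015, mid = 0.040, late = 0.015),
                regenB  = c(early = 0.010, mid = 0.035, late = 0.012),
                nonregen = c(early = 0.045, mid = 0.020, late = 0.008))
  m <- round(frac * n_genes)
  storage.mode(m) <- "integer"
  m
}

#' Configuration of the synthetic experiment generator
#'
#' Defaults describe the emulated study: a duplicated-genome transcriptome
#' with L/S homeolog pairs (S copies expressed at half the L level),
#' lognormal baseline expression on the FPKM scale, negative-binomial
#' replicate counts at 30 million aligned reads per sample, a
#' 17-condition / 51-sample design, planted tissue-specific injury
#' responses peaking at the mid phase in regenerative and the early phase
#' in non-regenerative tissue, 50 planted DESR genes (same-sign injury
#' response in both regenerative tissues at the mid time point, none in
#' the non-regenerative tissue) of which 20 respond in the opposite
#' direction in the non-regenerative tissue.
#'
#' @param n_genes number of genes (default 10000).
#' @param homeolog_pair_fraction fraction of genes belonging to an L/S
#'   pair (default 0.55).
#' @param baseline_log10_mean,baseline_log10_sd lognormal (base-10)
#'   baseline expression parameters before rescaling to the FPKM scale.
#' @param s_homeolog_factor multiplicative baseline factor for S homeologs
#'   (default 0.5; L copies are the higher-expressed ones).
#' @param nb_dispersion negative-binomial dispersion phi, with
#'   var = mu + phi * mu^2 (default 0.05).
#' @param library_size aligned reads per sample (default 30e6).
#' @param design a [study_design] (default [design_template()]).
#' @param temporal_profile tissues x time points matrix of planted
#'   tissue-specific DE gene counts (default
#'   [default_temporal_profile()]).
#' @param lfc_range range of |log2 fold-change| for tissue-specific
#'   planted effects (default c(0.3, 3)).
#' @param n_desr number of planted DESR genes (default 50).
#' @param desr_log2fc |log2 fold-change| of planted DESR effects
#'   (default 2).
#' @param desr_time time point of the planted DESR response
#'   (default "mid", the peak regenerative phase).
#' @param desr_up_fraction probability a planted DESR gene is
#'   up-regulated (default 253/324, the up/total ratio of the study's
#'   gene lists).
#' @param n_opposing planted DESR genes additionally given the
#'   opposite-sign effect in the non-regenerative tissue (default 20).
#' @param min_expressed_fpkm planted genes are drawn from genes whose
#'   baseline is at least this FPKM (default 1), so planted responses
#'   concern actively expressed genes.
#' @param max_planted_share upper bound on the library share (expected
#'   read fraction) of a gene carrying a planted effect (default 0.01).
#'   A fold-change planted on a gene that dominates the library would
#'   shift every other gene's FPKM through the per-sample total — a
#'   compositional artifact that count-based pipelines remove by
#'   cross-sample normalization, which the plain FPKM definition does
#'   not; injury-response genes are modelled as ordinary expressed
#'   genes, not extreme-abundance outliers.
#' @param seed root seed for all randomness (default 1).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 10000L,
                              homeolog_pair_fraction = 0.55,
                              baseline_log10_mean = 0.5,
                              baseline_log10_sd = 0.8,
                              s_homeolog_factor = 0.5,
                              nb_dispersion = 0.05,
                              library_size = 30e6,
                              design = design_template(),
                              temporal_profile =
                                default_temporal_profile(n_genes),
                              lfc_range = c(0.3, 3),
                              n_desr = 50L,
                              desr_log2fc = 2,
                              desr_time = "mid",
                              desr_up_fraction = 253 / 324,
                              n_opposing = 20L,
                              min_expressed_fpkm = 1,
                              max_planted_share = 0.01,
                              seed = 1L) {
  stopifnot(n_genes >= 10, homeolog_pair_fraction >= 0,
            homeolog_pair_fraction <= 1, nb_dispersion > 0,
            library_size > 0, n_desr >= 0, n_opposing >= 0,
            n_opposing <= n_desr, desr_log2fc >= 0,
            desr_time %in% TIME_POINTS,
            all(rownames(temporal_profile) == TISSUES),
            all(colnames(temporal_profile) == TIME_POINTS))
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

# internal: build the synthetic gene model
sim_gene_model <- function(cfg) {
  with_seed(sub_seed(cfg$seed, 1L), {
    n <- cfg$n_genes
    n_pairs <- floor(n * cfg$homeolog_pair_fraction / 2)
    n_single <- n - 2L * n_pairs
    stems <- sprintf("g%05d", seq_len(n_pairs + n_single))
    gid <- c(paste0(stems[seq_len(n_pairs)], ".L"),
             paste0(stems[seq_len(n_pairs)], ".S"),
             if (n_single > 0L) paste0(stems[n_pairs + seq_len(n_single)],
                                       ".L"))
    tag <- c(rep("L", n_pairs), rep("S", n_pairs), rep("L", n_single))
    partner <- c(paste0(stems[seq_len(n_pairs)], ".S"),
                 paste0(stems[seq_len(n_pairs)], ".L"),
                 rep(NA_character_, n_single))
    chrom_no <- sample(1:9, length(gid), replace = TRUE)
    chrom <- paste0("chr", chrom_no, tag)
    len <- pmax(200L, as.integer(round(stats::rlnorm(
      length(gid), meanlog = log(1500), sdlog = 0.6))))
    gene_model(data.frame(
      gene_id = gid, symbol = sub("\\.[LS]$", "", gid),
      homeolog_tag = tag, partner_id = partner, chrom = chrom,
      exonic_length_bp = len, stringsAsFactors = FALSE))
  })
}

# internal: baseline FPKM per gene, rescaled so that sum(fpkm * kb) = 1e6,
# i.e. nominal baselines are on the FPKM scale of a library in which these
# genes account for all aligned reads
sim_baseline <- function(cfg, model) {
  with_seed(sub_seed(cfg$seed, 2L), {
    b <- 10^stats::rnorm(nrow(model), cfg$baseline_log10_mean,
                         cfg$baseline_log10_sd)
    b[model$homeolog_tag == "S"] <- b[model$homeolog_tag == "S"] *
      cfg$s_homeolog_factor
    b * 1e6 / sum(b * model$exonic_length_bp / 1e3)
  })
}

# internal: planted effect table (gene_id, tissue, time_point, log2fc,
# class in {tissue_specific, desr, opposing_nr})
sim_planted <- function(cfg, model, baseline) {
  with_seed(sub_seed(cfg$seed, 3L), {
    share <- baseline * model$exonic_length_bp / 1e3 / 1e6
    eligible <- model$gene_id[baseline >= cfg$min_expressed_fpkm &
                                share <= cfg$max_planted_share]
    need <- cfg$n_desr + sum(cfg$temporal_profile)
    if (need > length(eligible))
      stop("not enough expressed genes to plant ", need, " effects")
    pool <- sample(eligible, need)
    out <- list()
    take <- function(k) {
      got <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      got
    }
    if (cfg$n_desr > 0L) {
      desr_genes <- take(cfg$n_desr)
      sign <- ifelse(stats::runif(cfg$n_desr) < cfg$desr_up_fraction, 1, -1)
      lfc <- sign * cfg$desr_log2fc
      for (tis in c("regenA", "regenB"))
        out[[length(out) + 1L]] <- data.frame(
          gene_id = desr_genes, tissue = tis, time_point = cfg$desr_time,
          log2fc = lfc, class = "desr", stringsAsFactors = FALSE)
      if (cfg$n_opposing > 0L) {
        opp <- seq_len(cfg$n_opposing)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = desr_genes[opp], tissue = "nonregen",
          time_point = cfg$desr_time, log2fc = -lfc[opp],
          class = "opposing_nr", stringsAsFactors = FALSE)
      }
    }
    for (tis in TISSUES) {
      for (tp in TIME_POINTS) {
        k <- cfg$temporal_profile[tis, tp]
        if (k == 0L) next
        g <- take(k)
        mag <- stats::runif(k, cfg$lfc_range[1L], cfg$lfc_range[2L])
        sgn <- ifelse(stats::runif(k) < 0.5, 1, -1)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, tissue = tis, time_point = tp, log2fc = sgn * mag,
          class = "tissue_specific", stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate a full synthetic experiment with planted truth
#'
#' Generates the gene model, a raw count matrix over the configured
#' design, and a truth table. For gene g in sample s the expected count is
#' `mu = baseline_fpkm[g] * 2^effect * exonic_length_kb[g] *
#' library_size / 1e6`, where `effect` is the planted log2 fold-change if
#' s is an injury sample of a (tissue, time point) carrying a planted
#' effect for g, and counts are drawn negative-binomial with dispersion
#' `nb_dispersion`. Identical configuration and seed give identical
#' output.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `model` ([gene_model]), `counts`
#'   ([count_matrix]), `design` ([study_design]), `truth` (per
#'   (gene, tissue, time_point) true log2fc with `desr_flag` and
#'   `opposing_flag`), `planted` (the compact planted-effect table) and
#'   `baseline_fpkm`.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  model <- sim_gene_model(cfg)
  baseline <- sim_baseline(cfg, model)
  planted <- sim_planted(cfg, model, baseline)
  if (!is.null(planted) && !all(planted$gene_id %in% model$gene_id))
    stop("planted gene id not in model")
  design <- cfg$design
  n <- nrow(model)
  len_kb <- model$exonic_length_bp / 1e3
  mu0 <- baseline * len_kb * cfg$library_size / 1e6
  counts <- with_seed(sub_seed(cfg$seed, 4L), {
    m <- matrix(0, n, nrow(design),
                dimnames = list(model$gene_id, design$sample_id))
    for (j in seq_len(nrow(design))) {
      mu <- mu0
      if (design$condition[j] == "injury" && !is.null(planted)) {
        hit <- planted$tissue == design$tissue[j] &
          planted$time_point == design$time_point[j]
        if (any(hit)) {
          idx <- match(planted$gene_id[hit], model$gene_id)
          mu[idx] <- mu[idx] * 2^planted$log2fc[hit]
        }
      }
      m[, j] <- stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
    }
    m
  })
  truth <- expand.grid(gene_id = model$gene_id, tissue = TISSUES,
                       time_point = TIME_POINTS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$true_log2fc <- 0
  if (!is.null(planted)) {
    key_t <- paste(truth$gene_id, truth$tissue, truth$time_point)
    key_p <- paste(planted$gene_id, planted$tissue, planted$time_point)
    idx <- match(key_t, key_p)
    truth$true_log2fc[!is.na(idx)] <- planted$log2fc[idx[!is.na(idx)]]
    desr_genes <- unique(planted$gene_id[planted$class == "desr"])
    opp_genes <- unique(planted$gene_id[planted$class == "opposing_nr"])
    truth$desr_flag <- truth$gene_id %in% desr_genes &
      truth$time_point == cfg$desr_time
    truth$opposing_flag <- truth$gene_id %in% opp_genes &
      truth$time_point == cfg$desr_time
  } else {
    truth$desr_flag <- FALSE
    truth$opposing_flag <- FALSE
  }
  list(model = model, counts = count_matrix(counts), design = design,
       truth = truth, planted = planted, baseline_fpkm = baseline)
}

#' Simulate read alignment records with homeolog ambiguity
#'
#' Every read originates from one true source gene, drawn uniformly from
#' the gene model. A read whose source gene has a homeolog partner may be
#' flagged as a potential duplicate alignment: the partner then receives
#' a second record whose score is lower by `score_margin`, or exactly
#' tied with probability `tie_prob`. `ambiguity_prob` is the marginal
#' flagged fraction over all reads (the quantity reported for the real
#' data), so the per-read flagging probability among partnered genes is
#' `ambiguity_prob` divided by the partnered fraction of the gene model;
#' it is an error for that quotient to exceed 1.
#'
#' @param model a [gene_model] with homeolog pairs.
#' @param n_reads number of reads (default 10000).
#' @param ambiguity_prob expected fraction of all reads flagged as
#'   potential duplicates (default 0.096, the study's observed fraction).
#' @param tie_prob probability an ambiguous read's two scores tie exactly
#'   (default 0.08: under a tenth of potential duplicates).
#' @param score_base mean primary alignment score (default 40).
#' @param score_margin score deficit of the partner record when not tied
#'   (default 5).
#' @param seed RNG seed.
#' @return list with `records` (data.frame read_id, gene_id, score) and
#'   `truth` (data.frame read_id, true_gene).
#' @export
simulate_alignment_records <- function(model, n_reads = 10000L,
                                       ambiguity_prob = 0.096,
                                       tie_prob = 0.08,
                                       score_base = 40, score_margin = 5,
                                       seed = 1L) {
  stopifnot(ambiguity_prob >= 0, ambiguity_prob <= 1,
            tie_prob >= 0, tie_prob <= 1, n_reads >= 1)
  frac_partnered <- mean(!is.na(model$partner_id))
  p_cond <- if (ambiguity_prob == 0) 0 else ambiguity_prob / frac_partnered
  if (p_cond > 1)
    stop("ambiguity_prob ", ambiguity_prob, " exceeds the partnered gene ",
         "fraction ", signif(frac_partnered, 3), " of the model")
  with_seed(seed, {
    src_idx <- sample.int(nrow(model), n_reads, replace = TRUE)
    src <- model$gene_id[src_idx]
    partner <- model$partner_id[src_idx]
    score <- round(score_base + stats::rnorm(n_reads, 0, 2), 2)
    rid <- sprintf("r%07d", seq_len(n_reads))
    ambiguous <- !is.na(partner) & stats::runif(n_reads) < p_cond
    tied <- ambiguous & stats::runif(n_reads) < tie_prob
    p_score <- ifelse(tied, score, score - score_margin)
    records <- rbind(
      data.frame(read_id = rid, gene_id = src, score = score,
                 stringsAsFactors = FALSE),
      data.frame(read_id = rid[ambiguous], gene_id = partner[ambiguous],
                 score = p_score[ambiguous], stringsAsFactors = FALSE))
    records <- records[order(records$read_id, records$gene_id), ]
    rownames(records) <- NULL
    list(records = records,
         truth = data.frame(read_id = rid, true_gene = src,
                            stringsAsFactors = FALSE))
  })
}
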