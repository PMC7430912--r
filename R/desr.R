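# The three-way comparative filter: genes Differentially Expressed in
# Successful Regeneration (DESR) are significant in the same direction in
# both axon-regenerative tissues and not in that direction in the
# non-regenerative tissue at the same time point.

de_genes <- function(res, direction) res$gene_id[res$status == direction]

#' Extract the DESR set at one time point
#'
#' Direction-aware set filter over the three tissues' DE results:
#' `up_genes = (UP in regenA) intersect (UP in regenB) minus
#' (UP in nonregen)`, and analogously for `down_genes`. Genes significant
#' in both regenerative tissues but with opposite signs are reported
#' separately as `discordant_genes`. Members of `up_genes` that are
#' significantly DOWN in the non-regenerative tissue (and vice versa) are
#' additionally flagged as `opposing_genes` — they remain DESR genes,
#' since the removal is performed per direction.
#'
#' @param regenA,regenB,nonregen `de_result` objects for the same time
#'   point (tissue attributes must match the argument names).
#' @return a `desr_set`: list with `time_point`, `up_genes`,
#'   `down_genes`, `discordant_genes`, `opposing_genes`, and `per_tissue`
#'   (the three underlying DE tables, for reporting).
#' @export
extract_desr <- function(regenA, regenB, nonregen) {
  tp <- check_three_way(regenA, regenB, nonregen)
  upA <- de_genes(regenA, "UP"); upB <- de_genes(regenB, "UP")
  dnA <- de_genes(regenA, "DOWN"); dnB <- de_genes(regenB, "DOWN")
  upN <- de_genes(nonregen, "UP"); dnN <- de_genes(nonregen, "DOWN")
  up <- sort(setdiff(intersect(upA, upB), upN))
  down <- sort(setdiff(intersect(dnA, dnB), dnN))
  discordant <- sort(union(intersect(upA, dnB), intersect(dnA, upB)))
  opposing <- sort(c(intersect(up, dnN), intersect(down, upN)))
  out <- list(time_point = tp, up_genes = up, down_genes = down,
              discordant_genes = discordant, opposing_genes = opposing,
              per_tissue = list(regenA = regenA, regenB = regenB,
                                nonregen = nonregen))
  class(out) <- "desr_set"
  out
}

#' @export
print.desr_set <- function(x, ...) {
  cat(sprintf(
    "DESR set (%s): %d up, %d down, %d opposing, %d discordant\n",
    x$time_point, length(x$up_genes), length(x$down_genes),
    length(x$opposing_genes), length(x$discordant_genes)))
  invisible(x)
}

#' Tabulate the 7 overlap regions among the three tissues
#'
#' Counts of UP and DOWN genes in every non-empty membership region of
#' the three significant sets (the regions of an UpSet plot). The
#' regenA-and-regenB-only region equals the DESR up/down sets of
#' [extract_desr()].
#'
#' @param regenA,regenB,nonregen `de_result` objects at one time point.
#' @return an `overlap_table` data.frame: `time_point`, `region` (e.g.
#'   `"regenA&regenB"`), `up_count`, `down_count`.
#' @export
tabulate_overlaps <- function(regenA, regenB, nonregen) {
  tp <- check_three_way(regenA, regenB, nonregen)
  regions <- c("regenA", "regenB", "nonregen",
               "regenA&regenB", "regenA&nonregen", "regenB&nonregen",
               "regenA&regenB&nonregen")
  count_dir <- function(direction) {
    sets <- list(regenA = de_genes(regenA, direction),
                 regenB = de_genes(regenB, direction),
                 nonregen = de_genes(nonregen, direction))
    all_genes <- unique(unlist(sets))
    member <- vapply(sets, function(s) all_genes %in% s,
                     logical(length(all_genes)))
    if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L)
    key <- apply(member, 1L, function(m)
      paste(names(sets)[m], collapse = "&"))
    vapply(regions, function(r) sum(key == r), 0L)
  }
  out <- data.frame(time_point = tp, region = regions,
                    up_count = count_dir("UP"),
                    down_count = count_dir("DOWN"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("overlap_table", "data.frame")
  out
}

#' Temporal summary of differential expression across all contrasts
#'
#' Per (tissue, time point) UP and DOWN counts (L and S homeologs tallied
#' separately), the percentage of the annotated genome each total
#' represents, and each tissue's peak time point (ties flagged).
#'
#' @param results named list of `de_result` covering every tissue x time
#'   point combination ("tissue.time_point" names, as produced by
#'   [test_all_contrasts()]).
#' @param genome_size annotated genes used as 100% for the percentage
#'   figures (default 24382).
#' @return a `temporal_summary`: list with `counts` (data.frame tissue,
#'   time_point, n_up, n_down, n_total, pct_genome) and `peaks`
#'   (data.frame tissue, peak_time_point, tie).
#' @export
temporal_summary <- function(results, genome_size = 24382) {
  needed <- as.vector(outer(TISSUES, TIME_POINTS, paste, sep = "."))
  missing <- setdiff(needed, names(results))
  if (length(missing) > 0L)
    stop("missing contrast(s): ", paste(missing, collapse = ", "))
  counts <- do.call(rbind, lapply(needed, function(nm) {
    res <- results[[nm]]
    n_up <- sum(res$status == "UP")
    n_down <- sum(res$status == "DOWN")
    data.frame(tissue = attr(res, "tissue"),
               time_point = attr(res, "time_point"),
               n_up = n_up, n_down = n_down, n_total = n_up + n_down,
               pct_genome = round(100 * (n_up + n_down) / genome_size, 1),
               stringsAsFactors = FALSE)
  }))
  peaks <- do.call(rbind, lapply(TISSUES, function(tis) {
    sub <- counts[counts$tissue == tis, ]
    mx <- max(sub$n_total)
    at <- sub$time_point[sub$n_total == mx]
    data.frame(tissue = tis,
               peak_time_point = if (mx == 0L) NA_character_ else at[1L],
               tie = length(at) > 1L || mx == 0L,
               stringsAsFactors = FALSE)
  }))
  out <- list(counts = counts, peaks = peaks, genome_size = genome_size)
  class(out) <- "temporal_summary"
  out
}

#' @export
print.temporal_summary <- function(x, ...) {
  print(x$counts)
  for (i in seq_len(nrow(x$peaks)))
    cat(sprintf("%s peaks at: %s%s\n", x$peaks$tissue[i],
                x$peaks$peak_time_point[i],
                if (x$peaks$tie[i]) " (tie)" else ""))
  invisible(x)
}

#' Share of DESR genes among all differentially expressed genes
#'
#' Reported as a percentage rounded to one decimal, the reporting
#' convention of the summary tables (324 DESR among 12059 DE genes is
#' 2.7).
#'
#' @param n_desr number of DESR genes.
#' @param n_total_de total differentially expressed genes.
#' @return percentage, one decimal.
#' @export
desr_share <- function(n_desr, n_total_de) {
  stopifnot(n_desr >= 0, n_total_de > 0)
  round(100 * n_desr / n_total_de, 1)
}

#' Expected number of false DESR calls under the compound FDR argument
#'
#' A gene enters the DESR set only by passing the FDR criterion
#' independently in two experiments, so the expected false-discovery
#' level of the combined list is bounded by `alpha^2`, giving
#' `alpha^2 * n` expected false genes among n DESR calls (about 1 gene
#' for alpha = 0.05 and n = 324).
#'
#' @param alpha per-experiment FDR criterion, in (0, 1).
#' @param n_desr number of DESR genes.
#' @return list with `expected_real` (`alpha^2 * n_desr`) and
#'   `expected_rounded` (nearest integer).
#' @export
compound_false_count <- function(alpha, n_desr) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  stopifnot(n_desr >= 0)
  expected <- alpha^2 * n_desr
  list(expected_real = expected, expected_rounded = round(expected))
}

#' Evaluate recovered DESR calls against a simulation truth table
#'
#' @param desr a `desr_set`.
#' @param truth truth table from [simulate_experiment()].
#' @return list with `recall` (recovered planted / planted, at this time
#'   point), `empirical_fdr` (non-planted among calls), `n_called`,
#'   `n_planted`, and `opposing_match` (TRUE when opposing flags agree
#'   exactly with truth restricted to recovered genes).
#' @export
evaluate_desr <- function(desr, truth) {
  tp <- desr$time_point
  tt <- truth[truth$time_point == tp & truth$tissue == "regenA", ]
  planted <- tt$gene_id[tt$desr_flag]
  planted_opp <- tt$gene_id[tt$opposing_flag]
  called <- c(desr$up_genes, desr$down_genes)
  n_called <- length(called)
  recall <- if (length(planted) == 0L) NA_real_ else
    length(intersect(called, planted)) / length(planted)
  fdr <- if (n_called == 0L) 0 else
    length(setdiff(called, planted)) / n_called
  recovered <- intersect(called, planted)
  opposing_match <- setequal(intersect(desr$opposing_genes, recovered),
                             intersect(planted_opp, recovered))
  list(recall = recall, empirical_fdr = fdr, n_called = n_called,
       n_planted = length(planted), opposing_match = opposing_match)
}
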