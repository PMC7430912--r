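# Resolution of reads with duplicate candidate alignments between L/S
# homeolog partners: the strictly higher-scoring alignment wins; exact
# ties are distributed uniformly at random between the two homeologs.

#' Resolve duplicate homeolog alignments into per-gene counts
#'
#' Each read is assigned to exactly one gene. Reads with a single
#' candidate keep it; reads with two candidate records (which must be
#' homeolog partners) go to the strictly higher score, and exact score
#' ties are broken uniformly at random with the seeded generator. Reads
#' with more than two candidates, or whose candidates are not homeolog
#' partners, are a hard error: the assignment rule is defined only for
#' the duplicated-genome two-homeolog case.
#'
#' @param records data.frame with columns `read_id`, `gene_id`, `score`.
#' @param model a [gene_model] supplying the partner relation.
#' @param seed RNG seed for tie-breaking.
#' @return an `assignment_report`: list with `n_reads`,
#'   `n_flagged_duplicate`, `n_score_resolved`, `n_random_resolved`, and
#'   `counts` (named vector over all model genes; sums to `n_reads`).
#' @export
resolve_duplicates <- function(records, model, seed = 1L) {
  stopifnot(all(c("read_id", "gene_id", "score") %in% names(records)))
  if (any(!is.finite(records$score))) stop("non-finite alignment score")
  unknown <- setdiff(records$gene_id, model$gene_id)
  if (length(unknown) > 0L)
    stop("alignment record(s) refer to unknown gene(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  ord <- order(records$read_id)
  rid <- records$read_id[ord]
  gid <- records$gene_id[ord]
  sc <- records$score[ord]
  runs <- rle(rid)
  if (any(runs$lengths > 2L))
    stop("read(s) with more than 2 candidate alignments: ",
         paste(utils::head(runs$values[runs$lengths > 2L], 5L),
               collapse = ", "))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dup <- runs$lengths == 2L
  assigned <- gid[starts]                       # unique reads: sole record
  n_random <- 0L
  if (any(dup)) {
    i1 <- starts[dup]
    i2 <- ends[dup]
    pmap <- stats::setNames(model$partner_id, model$gene_id)
    not_partners <- is.na(pmap[gid[i1]]) | pmap[gid[i1]] != gid[i2]
    if (any(not_partners))
      stop("candidates of read(s) are not homeolog partners: ",
           paste(utils::head(runs$values[dup][not_partners], 5L),
                 collapse = ", "))
    win <- ifelse(sc[i1] > sc[i2], gid[i1],
                  ifelse(sc[i2] > sc[i1], gid[i2], NA_character_))
    tie <- is.na(win)
    n_random <- sum(tie)
    if (n_random > 0L) {
      pick <- with_seed(seed,
                        stats::runif(n_random) < 0.5)
      win[tie] <- ifelse(pick, gid[i1[tie]], gid[i2[tie]])
    }
    assigned[dup] <- win
  }
  counts <- stats::setNames(numeric(nrow(model)), model$gene_id)
  tab <- table(assigned)
  counts[names(tab)] <- as.numeric(tab)
  report <- list(n_reads = length(runs$values),
                 n_flagged_duplicate = sum(dup),
                 n_score_resolved = sum(dup) - n_random,
                 n_random_resolved = n_random,
                 counts = counts)
  class(report) <- "assignment_report"
  report
}

#' Fraction of reads flagged as potential duplicate alignments
#' @param report an `assignment_report` from [resolve_duplicates()].
#' @return `n_flagged_duplicate / n_reads`.
#' @export
duplicate_fraction <- function(report) {
  stopifnot(inherits(report, "assignment_report"))
  if (report$n_reads == 0L) stop("report contains no reads")
  report$n_flagged_duplicate / report$n_reads
}

#' @export
print.assignment_report <- function(x, ...) {
  cat(sprintf(
    "homeolog assignment: %d reads, %d flagged duplicate (%.1f%%), %d by score, %d random\n",
    x$n_reads, x$n_flagged_duplicate, 100 * duplicate_fraction(x),
    x$n_score_resolved, x$n_random_resolved))
  invisible(x)
}
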