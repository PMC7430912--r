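# FPKM quantification and the density-based active-expression threshold.

#' Compute FPKM from raw counts
#'
#' `fpkm[g, s] = counts[g, s] * 1e9 / (exonic_length_bp[g] *
#' total_aligned[s])` — fragments per kilobase of exon per million mapped
#' reads, so expression is comparable across genes of different lengths
#' and samples of different depth.
#'
#' @param counts a [count_matrix].
#' @param model a [gene_model] covering every matrix gene.
#' @return numeric matrix of class `fpkm_matrix` with the same axes and
#'   the `total_aligned` attribute carried over.
#' @export
compute_fpkm <- function(counts, model) {
  missing <- setdiff(rownames(counts), model$gene_id)
  if (length(missing) > 0L)
    stop("gene(s) missing from model: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  totals <- total_aligned(counts)
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals <= 0)) stop("total_aligned must be positive")
  len <- model$exonic_length_bp[match(rownames(counts), model$gene_id)]
  fpkm <- unclass(counts) * 1e9 / outer(len, totals)
  dimnames(fpkm) <- dimnames(counts)
  attr(fpkm, "total_aligned") <- totals
  class(fpkm) <- c("fpkm_matrix", class(fpkm))
  fpkm
}

#' Estimate the active-expression threshold from the gene-density histogram
#'
#' Per-gene FPKM is averaged across the given samples; zero-mean genes are
#' excluded (they sit below any positive threshold by construction) and a
#' Gaussian kernel density (Silverman bandwidth) of log10 mean FPKM is
#' evaluated on a fixed grid. On a bimodal density — a low unexpressed
#' mode and a high expressed mode — the threshold is the location of the
#' density minimum between the two highest modes, i.e. the inflection
#' between the two populations. On a unimodal density the configured
#' default is returned instead.
#'
#' @param expr an `fpkm_matrix`.
#' @param samples sample ids to average over (default: all columns).
#' @param default_threshold fallback threshold in FPKM (default 0.45).
#' @param min_genes minimum number of expressed genes required
#'   (default 100).
#' @param grid_n density grid size (default 512).
#' @param mode_min_height local maxima below this fraction of the global
#'   density maximum are not counted as modes (default 0.1).
#' @return a `threshold_estimate`: list with `threshold_fpkm`, `method`
#'   (`"density_minimum"` or `"configured_default"`) and `diagnostics`
#'   (grid, density, located minimum in log10 space).
#' @export
estimate_expression_threshold <- function(expr, samples = colnames(expr),
                                          default_threshold = 0.45,
                                          min_genes = 100L,
                                          grid_n = 512L,
                                          mode_min_height = 0.1) {
  m <- rowMeans(unclass(expr)[, samples, drop = FALSE])
  x <- log10(m[m > 0])
  if (length(x) < min_genes)
    stop("only ", length(x), " expressed genes; need at least ", min_genes)
  d <- stats::density(x, bw = "nrd0", n = grid_n)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_max & y >= mode_min_height * max(y))
  if (length(peaks) < 2L) {
    est <- list(threshold_fpkm = default_threshold,
                method = "configured_default",
                diagnostics = list(grid = d$x, density = y,
                                   minimum_log10 = NA_real_))
    class(est) <- "threshold_estimate"
    return(est)
  }
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  between <- seq(top2[1L], top2[2L])
  min_idx <- between[which.min(y[between])]
  est <- list(threshold_fpkm = 10^d$x[min_idx],
              method = "density_minimum",
              diagnostics = list(grid = d$x, density = y,
                                 minimum_log10 = d$x[min_idx]))
  class(est) <- "threshold_estimate"
  est
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("expression threshold: FPKM = %.4g (%s)\n",
              x$threshold_fpkm, x$method))
  invisible(x)
}
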