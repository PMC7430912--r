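# Eigenvector PCA of condition-level expression profiles. Conditions are
# the variables and genes the observations; each condition is represented
# by the (normalized) projection of its centered profile onto the first
# two principal axes, and the angle between two condition vectors
# measures how well their expression profiles are correlated (0 degrees:
# proportional; 90: uncorrelated; 180: anti-correlated).

#' Select the k most highly expressed genes
#'
#' @param expr an `fpkm_matrix` (or any numeric matrix with gene
#'   rownames).
#' @param k number of genes; clamped to the gene count with a warning.
#' @return character vector of gene ids, ordered by decreasing mean
#'   expression across samples, ties broken by lexicographic gene id.
#' @export
top_gene_selection <- function(expr, k) {
  stopifnot(k >= 2)
  if (k > nrow(expr)) {
    warning("k = ", k, " exceeds gene count ", nrow(expr), "; clamping")
    k <- nrow(expr)
  }
  m <- rowMeans(unclass(expr))
  ord <- order(-m, rownames(expr))
  rownames(expr)[ord][seq_len(k)]
}

#' PCA of condition (or replicate) expression profiles
#'
#' Expression is transformed as `log10(fpkm + pseudocount)`. In
#' `condition_eigenvectors` mode replicates are first averaged within
#' each condition (tissue, condition, time point); in `replicate_scatter`
#' mode each sample is kept. Each profile column is centered across
#' genes and the centered matrix is decomposed by SVD. Gene loadings are
#' the per-gene coordinates on PC1/PC2; each condition's vector is the
#' unit-normalized projection of its profile onto (PC1, PC2); explained
#' variances are the PC variances over genes. Component signs follow the
#' first-nonzero-loading-positive convention so results are reproducible
#' across linear-algebra backends.
#'
#' @param expr an `fpkm_matrix`.
#' @param design a [study_design] covering the matrix samples.
#' @param mode `"condition_eigenvectors"` (default) or
#'   `"replicate_scatter"`.
#' @param pseudocount added before the log (default 0.1, shared with the
#'   testing stage).
#' @param genes optional gene subset (e.g. from [top_gene_selection()]).
#' @return a `pca_result`: list with `conditions`, `loadings` (genes x
#'   2), `condition_vectors` (conditions x 2, unit rows),
#'   `explained_variance` (all components, non-increasing),
#'   `proportion_variance`, `pairwise_angles` (degrees), `mode`.
#' @export
condition_pca <- function(expr, design,
                          mode = c("condition_eigenvectors",
                                   "replicate_scatter"),
                          pseudocount = 0.1, genes = NULL) {
  mode <- match.arg(mode)
  E <- unclass(expr)
  if (!is.null(genes)) E <- E[genes, , drop = FALSE]
  X <- log10(E + pseudocount)
  if (mode == "condition_eigenvectors") {
    design <- design[design$sample_id %in% colnames(X), ]
    grp <- paste(design$tissue, design$condition,
                 ifelse(is.na(design$time_point), "all",
                        design$time_point), sep = ".")
    labels <- unique(grp)
    X <- vapply(labels, function(g)
      rowMeans(X[, design$sample_id[grp == g], drop = FALSE]),
      numeric(nrow(X)))
    colnames(X) <- labels
  }
  if (ncol(X) < 2L) stop("need at least 2 conditions for PCA")
  Xc <- sweep(X, 2L, colMeans(X))
  if (all(abs(Xc) < 1e-12)) stop("all-constant expression matrix")
  sv <- svd(Xc)
  # sign convention: first nonzero gene loading of each component positive
  for (k in seq_along(sv$d)) {
    u <- sv$u[, k]
    nz <- which(abs(u) > 1e-12)
    if (length(nz) > 0L && u[nz[1L]] < 0) {
      sv$u[, k] <- -sv$u[, k]
      sv$v[, k] <- -sv$v[, k]
    }
  }
  loadings <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2L)
  dimnames(loadings) <- list(rownames(X), c("PC1", "PC2"))
  proj <- sv$v[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2L)
  nrm <- sqrt(rowSums(proj^2))
  vec <- proj / ifelse(nrm == 0, 1, nrm)
  dimnames(vec) <- list(colnames(X), c("PC1", "PC2"))
  ev <- sv$d^2 / (nrow(X) - 1)
  names(ev) <- paste0("PC", seq_along(ev))
  dots <- vec %*% t(vec)
  angles <- acos(pmin(pmax(dots, -1), 1)) * 180 / pi
  diag(angles) <- 0
  dimnames(angles) <- list(colnames(X), colnames(X))
  out <- list(conditions = colnames(X), loadings = loadings,
              condition_vectors = vec, explained_variance = ev,
              proportion_variance = ev / sum(ev),
              pairwise_angles = angles, mode = mode)
  class(out) <- "pca_result"
  out
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA (%s): %d conditions, PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$mode, length(x$conditions),
              100 * x$proportion_variance[1L],
              100 * x$proportion_variance[2L]))
  invisible(x)
}

#' Write condition vectors and pairwise angles to TSV
#' @param pca a `pca_result`.
#' @param path output TSV path.
#' @export
write_pca_result <- function(pca, path) {
  vec <- pca$condition_vectors
  df <- data.frame(condition = rownames(vec), PC1 = vec[, 1L],
                   PC2 = vec[, 2L], stringsAsFactors = FALSE)
  ang <- pca$pairwise_angles
  for (cn in colnames(ang)) df[[paste0("angle_", cn)]] <- ang[, cn]
  write_tsv_stable(df, path)
}
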