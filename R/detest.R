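# Per-gene differential expression testing on replicate log2 fold-changes
# with Benjamini-Hochberg FDR and the below-threshold expression filter.

#' Specify one (tissue, time point) injury-vs-control contrast
#'
#' @param tissue,time_point contrast labels.
#' @param injury_samples,control_samples sample id vectors. In paired mode
#'   the two vectors must be the same length and aligned pair-by-pair.
#' @param paired use per-pair log2 ratios and a one-sample test (TRUE) or
#'   a two-sample test on log2 expression (FALSE).
#' @param alpha FDR significance criterion (default 0.05).
#' @param min_fpkm active-expression threshold; genes below it in both
#'   conditions are not tested (default 0.45).
#' @param pseudocount FPKM pseudocount stabilizing log ratios at zero
#'   counts (default 0.1).
#' @return list of class `contrast_spec`.
#' @export
contrast_spec <- function(tissue, time_point, injury_samples,
                          control_samples, paired, alpha = 0.05,
                          min_fpkm = 0.45, pseudocount = 0.1) {
  if (length(injury_samples) < 2L || length(control_samples) < 2L)
    stop("need at least 2 replicates per side")
  if (paired && length(injury_samples) != length(control_samples))
    stop("paired contrast requires pair-aligned sample lists of equal length")
  stopifnot(alpha > 0, alpha < 1, min_fpkm > 0, pseudocount > 0)
  spec <- list(tissue = tissue, time_point = time_point,
               injury_samples = injury_samples,
               control_samples = control_samples, paired = paired,
               alpha = alpha, min_fpkm = min_fpkm,
               pseudocount = pseudocount)
  class(spec) <- "contrast_spec"
  spec
}

#' Build the canonical contrasts of a study design
#'
#' One contrast per tissue and time point. Tissues whose injury samples
#' carry pair ids are tested paired against their matched controls;
#' otherwise the tissue's control group (shared across time points, as
#' for the non-regenerative tissue's single control group) is used
#' unpaired. Naive samples are never part of a contrast.
#'
#' @param design a [study_design].
#' @param alpha,min_fpkm,pseudocount passed to [contrast_spec()].
#' @return named list of `contrast_spec` ("tissue.time_point").
#' @export
contrasts_from_design <- function(design, alpha = 0.05, min_fpkm = 0.45,
                                  pseudocount = 0.1) {
  out <- list()
  for (tissue in TISSUES) {
    for (tp in TIME_POINTS) {
      inj <- design[design$tissue == tissue & design$condition == "injury" &
                      !is.na(design$time_point) & design$time_point == tp, ]
      if (nrow(inj) == 0L) next
      paired <- all(!is.na(inj$pair_id))
      if (paired) {
        ctl_idx <- match(inj$pair_id, design$pair_id[
          design$condition == "control"])
        ctl <- design$sample_id[design$condition == "control"][ctl_idx]
        if (anyNA(ctl))
          stop("unmatched pair_id in contrast ", tissue, ".", tp)
      } else {
        ctl <- design$sample_id[design$tissue == tissue &
                                  design$condition == "control"]
      }
      out[[paste(tissue, tp, sep = ".")]] <-
        contrast_spec(tissue, tp, inj$sample_id, ctl, paired,
                      alpha = alpha, min_fpkm = min_fpkm,
                      pseudocount = pseudocount)
    }
  }
  out
}

#' Benjamini-Hochberg step-up adjusted q values
#'
#' Ranks the p values and applies the step-up rule
#' `q_(i) = min_{j >= i} p_(j) * n / j`, clipped to 1, restoring the
#' original ordering. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p values in \[0, 1\] (NA allowed; NA
#'   entries receive NA and do not count toward n).
#' @return q values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

# internal: per-row one-sample t on a ratio matrix (df = ncol - 1).
# All-zero rows get p = 1; other zero-variance rows are untestable (NA).
row_one_sample_t <- function(R) {
  n <- ncol(R)
  m <- rowMeans(R)
  s <- sqrt(rowSums((R - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  zero_var <- s == 0
  p[zero_var & m == 0] <- 1
  p[zero_var & m != 0] <- NA_real_
  t[zero_var] <- NA_real_
  list(t = t, p = p)
}

# internal: per-row Welch two-sample t
row_welch_t <- function(Y1, Y0) {
  n1 <- ncol(Y1); n0 <- ncol(Y0)
  m1 <- rowMeans(Y1); m0 <- rowMeans(Y0)
  v1 <- rowSums((Y1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((Y0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(t), df = df)
  zero <- se2 == 0
  p[zero & m1 == m0] <- 1
  p[zero & m1 != m0] <- NA_real_
  t[zero] <- NA_real_
  list(t = t, p = p)
}

#' Test one contrast for differential expression
#'
#' Genes whose mean FPKM falls below `min_fpkm` in both the injury and
#' the control condition are not tested (`NOTEST`). For tested genes the
#' paired mode forms per-pair replicate ratios
#' `r_i = log2((fpkm_inj_i + pc) / (fpkm_ctrl_i + pc))` and tests their
#' mean against zero; the unpaired mode compares `log2(fpkm + pc)`
#' between the two groups. With `method = "moderated"` (default) the
#' per-gene variance is moderated across genes by empirical Bayes
#' (limma), pooling dispersion information over the transcriptome the way
#' count-based DE tools do; `method = "t"` is the plain replicate-level
#' t test (df = n - 1 one-sample in paired mode, Welch in unpaired mode),
#' which at 3 replicates has too few degrees of freedom to produce small
#' p values and is provided for reference and pedagogy. q values come
#' from [benjamini_hochberg()] over the tested genes of this contrast,
#' and a gene is `UP`/`DOWN` when `q <= alpha` with the matching sign of
#' its log2 fold-change, `NS` otherwise.
#'
#' @param expr an `fpkm_matrix` from [compute_fpkm()].
#' @param spec a [contrast_spec()].
#' @param method `"moderated"` (default) or `"t"`.
#' @return a `de_result` data.frame (gene_id, mean_fpkm_control,
#'   mean_fpkm_injury, log2fc, t, p, q, status) with attributes `tissue`,
#'   `time_point`, `alpha`, `method`.
#' @export
test_contrast <- function(expr, spec, method = c("moderated", "t")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "contrast_spec"))
  missing <- setdiff(c(spec$injury_samples, spec$control_samples),
                     colnames(expr))
  if (length(missing) > 0L)
    stop("sample(s) missing from expression matrix: ",
         paste(missing, collapse = ", "))
  E <- unclass(expr)
  inj <- E[, spec$injury_samples, drop = FALSE]
  ctl <- E[, spec$control_samples, drop = FALSE]
  if (any(!is.finite(inj)) || any(!is.finite(ctl)))
    stop("non-finite FPKM value in contrast ", spec$tissue, ".",
         spec$time_point)
  pc <- spec$pseudocount
  mean_inj <- rowMeans(inj)
  mean_ctl <- rowMeans(ctl)
  tested <- mean_inj >= spec$min_fpkm | mean_ctl >= spec$min_fpkm
  log2fc <- log2((mean_inj + pc) / (mean_ctl + pc))
  t_stat <- p <- rep(NA_real_, nrow(E))
  if (any(tested)) {
    if (spec$paired) {
      R <- log2(inj[tested, , drop = FALSE] + pc) -
        log2(ctl[tested, , drop = FALSE] + pc)
      if (method == "t") {
        r <- row_one_sample_t(R)
      } else {
        fit <- limma::eBayes(limma::lmFit(R, matrix(1, ncol(R), 1L)))
        r <- list(t = fit$t[, 1L], p = fit$p.value[, 1L])
      }
    } else {
      Y1 <- log2(inj[tested, , drop = FALSE] + pc)
      Y0 <- log2(ctl[tested, , drop = FALSE] + pc)
      if (method == "t") {
        r <- row_welch_t(Y1, Y0)
      } else {
        grp <- rep(c(1, 0), c(ncol(Y1), ncol(Y0)))
        fit <- limma::eBayes(limma::lmFit(cbind(Y1, Y0),
                                          cbind(1, grp)))
        r <- list(t = fit$t[, 2L], p = fit$p.value[, 2L])
      }
    }
    t_stat[tested] <- r$t
    p[tested] <- r$p
  }
  q <- rep(NA_real_, nrow(E))
  q[tested] <- benjamini_hochberg(p[tested])
  status <- rep("NS", nrow(E))
  status[!tested] <- "NOTEST"
  sig <- tested & !is.na(q) & q <= spec$alpha
  status[sig & log2fc > 0] <- "UP"
  status[sig & log2fc < 0] <- "DOWN"
  out <- data.frame(gene_id = rownames(E),
                    mean_fpkm_control = mean_ctl,
                    mean_fpkm_injury = mean_inj,
                    log2fc = log2fc, t = t_stat, p = p, q = q,
                    status = status, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, tissue = spec$tissue, time_point = spec$time_point,
            alpha = spec$alpha, method = method,
            class = c("de_result", "data.frame"))
}

#' Run all contrasts of a design
#' @param expr an `fpkm_matrix`.
#' @param design a [study_design].
#' @param ... passed to [contrasts_from_design()].
#' @param method testing method, see [test_contrast()].
#' @return named list of `de_result` ("tissue.time_point").
#' @export
test_all_contrasts <- function(expr, design, ...,
                               method = c("moderated", "t")) {
  method <- match.arg(method)
  specs <- contrasts_from_design(design, ...)
  lapply(specs, function(s) test_contrast(expr, s, method = method))
}
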