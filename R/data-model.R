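#' @keywords internal
"_PACKAGE"

TISSUES <- c("regenA", "regenB", "nonregen")
TIME_POINTS <- c("early", "mid", "late")
CONDITIONS <- c("injury", "control", "naive")
STATUS_LEVELS <- c("UP", "DOWN", "NS", "NOTEST")

#' Construct and validate a gene model table
#'
#' A gene model describes every gene of the (duplicated) genome: its
#' identifier, human-ortholog-style symbol, L/S homeolog tag, the identifier
#' of its homeolog partner (if any), chromosome, and exonic length in bases.
#' L and S homeologs are distinct genes throughout the pipeline; they are
#' never merged.
#'
#' @param df data.frame with columns `gene_id`, `symbol`, `homeolog_tag`
#'   (one of `"L"`, `"S"`, `"none"`), `partner_id` (NA when unpartnered),
#'   `chrom`, `exonic_length_bp` (positive integer).
#' @return the validated data.frame with class `gene_model`.
#' @export
gene_model <- function(df) {
  req <- c("gene_id", "symbol", "homeolog_tag", "partner_id", "chrom",
           "exonic_length_bp")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("gene model is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, req]
  df$gene_id <- as.character(df$gene_id)
  df$partner_id <- as.character(df$partner_id)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in gene model: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (!all(df$homeolog_tag %in% c("L", "S", "none")))
    stop("homeolog_tag must be one of 'L', 'S', 'none'")
  len <- df$exonic_length_bp
  if (any(!is.finite(len)) || any(len < 1) || any(len != round(len)))
    stop("exonic_length_bp must be a positive integer for every gene")
  df$exonic_length_bp <- as.integer(round(len))
  # partner relation must be symmetric: partner(partner(g)) == g
  has_p <- !is.na(df$partner_id) & df$partner_id != ""
  if (any(has_p)) {
    idx <- match(df$partner_id[has_p], df$gene_id)
    if (anyNA(idx))
      stop("partner_id refers to unknown gene(s): ",
           paste(df$partner_id[has_p][is.na(idx)], collapse = ", "))
    back <- df$partner_id[idx]
    bad <- back != df$gene_id[has_p] | is.na(back)
    if (any(bad))
      stop("asymmetric partner relation for: ",
           paste(df$gene_id[has_p][bad], collapse = ", "))
    if (any(df$partner_id[has_p] == df$gene_id[has_p]))
      stop("a gene cannot be its own homeolog partner")
  }
  rownames(df) <- df$gene_id
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Construct and validate a study design (sample sheet)
#'
#' Maps each sample to its tissue (`regenA` and `regenB` are the two
#' axon-regenerative tissues, `nonregen` the non-regenerative one),
#' condition (`injury`, `control`, or `naive` for an uninjured group used
#' only in ordination), time point (`early`, `mid`, `late`; NA for groups
#' shared across time points), replicate number, and an optional `pair_id`
#' linking an injury replicate to its matched control replicate.
#'
#' @param df data.frame with columns `sample_id`, `tissue`, `condition`,
#'   `time_point`, `replicate`, `pair_id`.
#' @return validated data.frame with class `study_design`.
#' @export
study_design <- function(df) {
  req <- c("sample_id", "tissue", "condition", "time_point", "replicate",
           "pair_id")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("study design is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, req]
  for (col in c("sample_id", "tissue", "condition", "time_point", "pair_id"))
    df[[col]] <- as.character(df[[col]])
  df$time_point[df$time_point %in% c("", "NA")] <- NA_character_
  df$pair_id[df$pair_id %in% c("", "NA")] <- NA_character_
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in study design")
  if (!all(df$tissue %in% TISSUES))
    stop("tissue must be one of: ", paste(TISSUES, collapse = ", "))
  if (!all(df$condition %in% CONDITIONS))
    stop("condition must be one of: ", paste(CONDITIONS, collapse = ", "))
  if (!all(is.na(df$time_point) | df$time_point %in% TIME_POINTS))
    stop("time_point must be one of: ", paste(TIME_POINTS, collapse = ", "),
         " or NA")
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate) | df$replicate < 1L))
    stop("replicate must be a positive integer")
  key <- paste(df$tissue, df$condition, df$time_point, df$replicate)
  if (anyDuplicated(key))
    stop("(tissue, condition, time_point, replicate) must be unique")
  pid <- df$pair_id[!is.na(df$pair_id)]
  for (p in unique(pid)) {
    sub <- df[!is.na(df$pair_id) & df$pair_id == p, ]
    ok <- nrow(sub) == 2L &&
      setequal(sub$condition, c("injury", "control")) &&
      length(unique(sub$tissue)) == 1L &&
      length(unique(sub$time_point)) == 1L
    if (!ok)
      stop("pair_id '", p, "' must join exactly one injury and one control ",
           "sample of the same tissue and time point")
  }
  rownames(df) <- df$sample_id
  class(df) <- c("study_design", "data.frame")
  df
}

#' Construct a count matrix with per-sample totals
#'
#' @param counts non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns (colnames are sample ids).
#' @param total_aligned per-sample total aligned reads; defaults to the
#'   column sums. Counts may not exceed the total of their sample.
#' @return the matrix with attribute `total_aligned` and class
#'   `count_matrix` prepended.
#' @export
count_matrix <- function(counts, total_aligned = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs gene rownames and sample colnames")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  if (is.null(total_aligned)) total_aligned <- colSums(counts)
  total_aligned <- total_aligned[colnames(counts)]
  if (anyNA(total_aligned) || any(total_aligned <= 0))
    stop("total_aligned must be positive for every sample")
  if (any(sweep(counts, 2L, total_aligned, ">")))
    stop("a count exceeds its sample's total_aligned")
  attr(counts, "total_aligned") <- total_aligned
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' Per-sample totals of a count or expression matrix
#' @param x a `count_matrix` or `fpkm_matrix`.
#' @return named numeric vector of total aligned reads per sample.
#' @export
total_aligned <- function(x) attr(x, "total_aligned")

# internal: validate three DE results share a time point and cover the
# three tissues
check_three_way <- function(regenA, regenB, nonregen) {
  res <- list(regenA = regenA, regenB = regenB, nonregen = nonregen)
  for (nm in names(res)) {
    if (!inherits(res[[nm]], "de_result"))
      stop("'", nm, "' is not a de_result")
    if (!identical(attr(res[[nm]], "tissue"), nm))
      stop("'", nm, "' argument carries tissue '",
           attr(res[[nm]], "tissue"), "'")
  }
  tps <- vapply(res, attr, "", "time_point")
  if (length(unique(tps)) != 1L)
    stop("mismatched time points across the three DE results: ",
         paste(tps, collapse = ", "))
  tps[[1L]]
}
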