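# Tabular I/O. The canonical exchange format is TSV with a header row;
# numbers are written with full precision so write -> read round-trips
# exactly and repeated writes are byte-identical.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, "")
  out
}

write_tsv_stable <- function(df, path, header_comment = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- character(0)
  if (!is.null(header_comment))
    lines <- paste0("# ", header_comment)
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) fmt_num(col)
    else {
      out <- as.character(col)
      out[is.na(out)] <- "NA"
      out
    }
  })
  body <- if (nrow(df) == 0L) character(0) else
    do.call(paste, c(cols, sep = "\t"))
  lines <- c(lines, paste(names(df), collapse = "\t"), body)
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a gene model from TSV or GTF
#'
#' The TSV must carry the header `gene_id, symbol, homeolog_tag,
#' partner_id, chrom, exonic_length_bp`. Alternatively a GTF file
#' (1-based inclusive coordinates) may be given, in which case
#' `exonic_length_bp` is computed as the length of the union of each
#' gene's exon intervals; symbols default to the gene id and homeolog
#' tags are taken from a trailing `.L`/`.S` suffix on the gene id, with
#' partners linked when both suffixed copies are present.
#'
#' @param path file path; a `.gtf` extension selects the GTF reader
#'   (requires the rtracklayer and GenomicRanges packages).
#' @return a [gene_model] data.frame.
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
    return(read_gene_model_gtf(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          na.strings = c("NA", ""), comment.char = "#")
  df$exonic_length_bp <- as.numeric(df$exonic_length_bp)
  gene_model(df)
}

read_gene_model_gtf <- function(path) {
  for (pkg in c("rtracklayer", "GenomicRanges"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("GTF input requires the ", pkg, " package")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("GTF contains no exon records")
  ids <- as.character(gr$gene_id)
  spl <- split(gr, ids)
  lens <- vapply(spl, function(g)
    sum(GenomicRanges::width(GenomicRanges::reduce(g))), 0)
  chroms <- vapply(spl, function(g)
    as.character(GenomicRanges::seqnames(g))[1L], "")
  gid <- names(spl)
  tag <- ifelse(grepl("\\.L$", gid), "L",
                ifelse(grepl("\\.S$", gid), "S", "none"))
  stem <- sub("\\.[LS]$", "", gid)
  partner <- rep(NA_character_, length(gid))
  for (i in seq_along(gid)) {
    if (tag[i] == "none") next
    other <- paste0(stem[i], if (tag[i] == "L") ".S" else ".L")
    if (other %in% gid) partner[i] <- other
  }
  gene_model(data.frame(
    gene_id = gid, symbol = stem, homeolog_tag = tag, partner_id = partner,
    chrom = chroms, exonic_length_bp = lens, stringsAsFactors = FALSE))
}

#' Write a gene model to TSV
#' @param model a [gene_model].
#' @param path output path.
#' @export
write_gene_model <- function(model, path) {
  write_tsv_stable(as.data.frame(model), path)
}

#' Read a raw count matrix from TSV
#'
#' First column must be `gene_id`; remaining columns are sample ids. Every
#' sample of the design must be present (extra columns are dropped with a
#' warning). Totals default to column sums unless a two-column sidecar TSV
#' (`sample_id`, `total_aligned`) is supplied.
#'
#' @param path counts TSV.
#' @param design a [study_design]; its samples define the matrix columns.
#' @param totals_path optional totals sidecar TSV.
#' @return a [count_matrix].
#' @export
read_counts <- function(path, design, totals_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#")
  if (names(df)[1L] != "gene_id") stop("first column must be gene_id")
  missing <- setdiff(design$sample_id, names(df))
  if (length(missing) > 0L)
    stop("design sample(s) missing from count matrix: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df)[-1L], design$sample_id)
  if (length(extra) > 0L)
    warning("dropping count columns absent from design: ",
            paste(extra, collapse = ", "))
  m <- as.matrix(df[, design$sample_id, drop = FALSE])
  rownames(m) <- as.character(df$gene_id)
  if (any(m < 0)) stop("negative count in ", path)
  totals <- NULL
  if (!is.null(totals_path)) {
    td <- utils::read.delim(totals_path, header = TRUE, sep = "\t")
    totals <- stats::setNames(as.numeric(td$total_aligned),
                              as.character(td$sample_id))
    missing_t <- setdiff(design$sample_id, names(totals))
    if (length(missing_t) > 0L)
      stop("totals sidecar is missing sample(s): ",
           paste(missing_t, collapse = ", "))
  }
  count_matrix(m, totals)
}

#' Write a count matrix (and optional totals sidecar) to TSV
#' @param counts a [count_matrix].
#' @param path output TSV path.
#' @param totals_path optional path for a totals sidecar.
#' @export
write_counts <- function(counts, path, totals_path = NULL) {
  df <- data.frame(gene_id = rownames(counts), stringsAsFactors = FALSE)
  for (s in colnames(counts)) df[[s]] <- counts[, s]
  write_tsv_stable(df, path)
  if (!is.null(totals_path))
    write_tsv_stable(data.frame(sample_id = colnames(counts),
                                total_aligned = total_aligned(counts)),
                     totals_path)
  invisible(path)
}

#' Read a sample sheet (CSV) into a study design
#' @param path CSV with columns sample_id, tissue, condition, time_point,
#'   replicate, pair_id.
#' @return a [study_design].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        na.strings = c("NA", ""))
  study_design(df)
}

#' Write a study design to CSV
#' @param design a [study_design].
#' @param path output CSV path.
#' @export
write_design <- function(design, path) {
  df <- as.data.frame(design)
  df[] <- lapply(df, as.character)
  df[is.na(df)] <- "NA"
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = ","),
               apply(df, 1L, paste, collapse = ",")), con, sep = "\n")
  invisible(path)
}

#' Write a per-gene differential expression result table to TSV
#'
#' Columns mirror the downstream analysis tables of the study design:
#' gene, control and injury mean FPKM, log2 fold-change, p, q, and status.
#'
#' @param res a `de_result` as returned by [test_contrast()].
#' @param path output TSV path.
#' @param header_comment optional `#` comment written as the first line.
#' @export
write_de_result <- function(res, path, header_comment = NULL) {
  df <- data.frame(gene = res$gene_id,
                   fpkm_ctrl = res$mean_fpkm_control,
                   fpkm_inj = res$mean_fpkm_injury,
                   log2fc = res$log2fc, p = res$p, q = res$q,
                   status = res$status, stringsAsFactors = FALSE)
  hc <- paste0("tissue=", attr(res, "tissue"),
               " time_point=", attr(res, "time_point"),
               if (!is.null(header_comment)) paste0(" ", header_comment))
  write_tsv_stable(df, path, header_comment = hc)
}

#' Read back a differential expression result written by [write_de_result()]
#' @param path TSV path.
#' @return a `de_result` data.frame.
#' @export
read_de_result <- function(path) {
  first <- readLines(path, n = 1L)
  tissue <- time_point <- NA_character_
  if (startsWith(first, "#")) {
    tissue <- sub(".*tissue=(\\S+).*", "\\1", first)
    time_point <- sub(".*time_point=(\\S+).*", "\\1", first)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  out <- data.frame(gene_id = as.character(df$gene),
                    mean_fpkm_control = df$fpkm_ctrl,
                    mean_fpkm_injury = df$fpkm_inj,
                    log2fc = df$log2fc, p = df$p, q = df$q,
                    status = as.character(df$status),
                    stringsAsFactors = FALSE)
  structure(out, tissue = tissue, time_point = time_point,
            class = c("de_result", "data.frame"))
}

#' Write a DESR set to TSV
#'
#' One row per member gene, with its direction, per-tissue log2
#' fold-changes and q values, and whether it is significantly regulated in
#' the opposing direction in the non-regenerative tissue.
#'
#' @param desr a `desr_set` from [extract_desr()].
#' @param path output TSV path.
#' @param header_comment optional comment line.
#' @export
write_desr_set <- function(desr, path, header_comment = NULL) {
  genes <- c(desr$up_genes, desr$down_genes)
  df <- data.frame(
    gene = genes,
    direction = rep(c("up", "down"),
                    c(length(desr$up_genes), length(desr$down_genes))),
    time_point = rep(desr$time_point, length(genes)),
    opposing = ifelse(genes %in% desr$opposing_genes, "yes", "no"),
    stringsAsFactors = FALSE)
  for (tis in TISSUES) {
    tab <- desr$per_tissue[[tis]]
    if (is.null(tab)) next
    idx <- match(genes, tab$gene_id)
    df[[paste0("log2fc_", tis)]] <- tab$log2fc[idx]
    df[[paste0("q_", tis)]] <- tab$q[idx]
  }
  if (nrow(df) == 0L)
    df <- df[, , drop = FALSE]
  write_tsv_stable(df, path, header_comment = header_comment)
}

#' Write a list summary as JSON
#' @param x a list of scalar values or simple vectors.
#' @param path output path.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
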