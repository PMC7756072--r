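#' Gene-by-sample count matrix with sample metadata
#'
#' The basic container used throughout the pipeline: a non-negative
#' integer matrix (genes in rows, samples in columns) together with
#' per-sample metadata. Conditions follow the study designs the package
#' supports: an injury time course (`injured`, `sham`, `healthy` with a
#' `timepoint` in days) and a paired cohort (`tumor`, `normal` with a
#' `pair_id` linking the two samples of one patient).
#'
#' @param counts integer-like matrix, genes x samples, with unique row and
#'   column names.
#' @param metadata data.frame with one row per sample and columns
#'   `sample_id`, `condition`, and optionally `timepoint`, `pair_id`,
#'   `stage`.
#' @return An object of class `count_matrix` with elements `counts` and
#'   `metadata` (rows ordered as the columns of `counts`).
#' @export
count_matrix <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene IDs in counts")
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample IDs in counts")
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("counts must be finite and non-negative")
  if (!is.data.frame(metadata) || !all(c("sample_id", "condition") %in% names(metadata)))
    stopf("metadata needs sample_id and condition columns")
  if (anyDuplicated(metadata$sample_id))
    stopf("duplicate sample IDs in metadata")
  if (!setequal(metadata$sample_id, colnames(counts)))
    stopf("metadata samples do not match count matrix columns")
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  ok <- c("injured", "sham", "healthy", "tumor", "normal")
  if (!all(metadata$condition %in% ok))
    stopf("unknown condition(s): %s",
          paste(setdiff(unique(metadata$condition), ok), collapse = ", "))
  # paired invariant: every tumor sample with a pair_id has its normal mate
  if (!is.null(metadata$pair_id)) {
    paired <- metadata[!is.na(metadata$pair_id) &
                         metadata$condition %in% c("tumor", "normal"), ]
    if (nrow(paired)) {
      tab <- table(paired$pair_id, factor(paired$condition, c("tumor", "normal")))
      if (any(tab[, "tumor"] != tab[, "normal"]))
        stopf("unmatched tumor/normal samples for pair(s): %s",
              paste(rownames(tab)[tab[, "tumor"] != tab[, "normal"]], collapse = ", "))
    }
  }
  structure(list(counts = counts, metadata = metadata), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$metadata$condition))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write / read the TSV count-matrix dialect
#'
#' Counts are written as a TSV with gene IDs in the first column
#' (`gene_id`) and sample IDs as the header; metadata as a sample table
#' (`sample_id`, `condition`, `timepoint`, `pair_id`, ...). Missing
#' metadata fields are written as `NA`.
#'
#' @param cm a [count_matrix()].
#' @param counts_path,metadata_path file paths.
#' @return `write_counts` returns the paths invisibly; `read_counts`
#'   returns a [count_matrix()].
#' @export
write_counts <- function(cm, counts_path, metadata_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$metadata, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, metadata_path) {
  df <- read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  meta <- read.delim(metadata_path)
  meta$sample_id <- as.character(meta$sample_id)
  count_matrix(counts, meta)
}

subset_samples <- function(cm, keep) {
  count_matrix(cm$counts[, keep, drop = FALSE],
               cm$metadata[match(keep, cm$metadata$sample_id), , drop = FALSE])
}
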