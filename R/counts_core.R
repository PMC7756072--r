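#' De-duplicate gene identifiers by inter-quartile range
#'
#' When several source rows map onto the same target identifier (the
#' Ensembl-to-Entrez collision typical of cohort count tables), the row
#' with the largest inter-quartile range of counts across samples is
#' kept and the others dropped. Ties are broken by larger total count,
#' then by lexicographically smaller source ID. The rule is applied
#' symmetrically: a source row mapping to several targets is a candidate
#' for each of them.
#'
#' @param cm a [count_matrix()] whose rownames are source IDs.
#' @param id_map data.frame with columns `source_id`, `target_id`
#'   (may be many:many).
#' @return a [count_matrix()] keyed by target IDs.
#' @export
dedupe_ids <- function(cm, id_map) {
  if (!nrow(id_map)) stopf("empty id map")
  if (!all(c("source_id", "target_id") %in% names(id_map)))
    stopf("id_map needs source_id and target_id columns")
  map <- id_map[id_map$source_id %in% rownames(cm$counts), , drop = FALSE]
  if (!nrow(map)) stopf("no id_map source IDs present in the count matrix")
  pick <- vapply(split(map$source_id, map$target_id), function(src) {
    src <- unique(src)
    iqr <- apply(cm$counts[src, , drop = FALSE], 1, IQR)
    tot <- rowSums(cm$counts[src, , drop = FALSE])
    src[order(-iqr, -tot, src)][1]
  }, character(1))
  counts <- cm$counts[pick, , drop = FALSE]
  rownames(counts) <- names(pick)
  count_matrix(counts, cm$metadata)
}

#' Filter weakly expressed genes
#'
#' Keeps genes with at least `min_cpm` counts per million in at least
#' `min_samples` samples. CPM is computed on raw library sizes: the
#' filter precedes normalization.
#'
#' @param cm a [count_matrix()].
#' @param min_cpm CPM threshold (kept if CPM >= min_cpm).
#' @param min_samples number of samples that must reach the threshold.
#' @return the filtered [count_matrix()]; idempotent.
#' @export
filter_low_expression <- function(cm, min_cpm = 1, min_samples = 3) {
  lib <- colSums(cm$counts)
  if (any(lib <= 0)) stopf("all library sizes must be positive")
  if (min_samples > ncol(cm$counts))
    stopf("min_samples exceeds the number of samples")
  cpm <- t(t(cm$counts) / lib) * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  count_matrix(cm$counts[keep, , drop = FALSE], cm$metadata)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors (Robinson--Oshlack): for
#' each sample, a precision-weighted mean of log-ratios against a
#' reference sample, after trimming `logratio_trim` of the M-values and
#' `sum_trim` of the A-values on each side; genes zero in either sample
#' are excluded, and factors are centered to geometric mean 1. The
#' reference is the sample whose CPM upper quartile is closest to the
#' mean upper quartile (`ref = "auto"`). Computation is delegated to
#' edgeR, the field implementation of TMM.
#'
#' @param cm a [count_matrix()], already expression-filtered.
#' @param logratio_trim,sum_trim two-sided trim fractions.
#' @param ref `"auto"` or a sample ID.
#' @return an object of class `norm_factors`: data.frame with
#'   `sample_id`, `lib_size`, `tmm_factor`, `effective_lib_size`.
#' @export
tmm_factors <- function(cm, logratio_trim = 0.3, sum_trim = 0.05, ref = "auto") {
  if (ncol(cm$counts) < 2) stopf("TMM needs at least two samples")
  ref_col <- if (identical(ref, "auto")) NULL else {
    i <- match(ref, colnames(cm$counts))
    if (is.na(i)) stopf("reference sample '%s' not found", ref)
    i
  }
  lib <- colSums(cm$counts)
  f <- edgeR::calcNormFactors(cm$counts, lib.size = lib, method = "TMM",
                              refColumn = ref_col,
                              logratioTrim = logratio_trim,
                              sumTrim = sum_trim)
  if (any(!is.finite(f)) || any(f <= 0))
    stopf("TMM failed: a sample shares no expressed genes with the reference")
  out <- data.frame(sample_id = colnames(cm$counts), lib_size = lib,
                    tmm_factor = f, effective_lib_size = lib * f,
                    row.names = NULL)
  class(out) <- c("norm_factors", "data.frame")
  out
}

#' Log2 counts per million
#'
#' `log2(count / effective_library_size * 1e6 + prior_count)`: CPM on
#' TMM-effective library sizes with a pseudo-CPM prior, so the transform
#' is finite everywhere and exactly invariant under a joint rescaling of
#' all counts and library sizes.
#'
#' @param cm a [count_matrix()].
#' @param factors matching [tmm_factors()] output.
#' @param prior_count prior on the CPM scale.
#' @return numeric matrix, genes x samples.
#' @export
log_cpm <- function(cm, factors, prior_count = 0.5) {
  if (!identical(factors$sample_id, colnames(cm$counts)))
    stopf("factors do not match the samples of the count matrix")
  eff <- factors$effective_lib_size
  log2(t(t(cm$counts) / eff) * 1e6 + prior_count)
}

#' Sample coordinates on principal components
#'
#' Samples are centered gene-wise and projected on the top
#' right-singular directions of the expression matrix; used for QC of
#' the simulated designs (timepoints and conditions should separate).
#'
#' @param expr expression matrix (genes x samples), e.g. [log_cpm()].
#' @param n_components number of components (<= min dimension).
#' @return list with `coords` (samples x components) and `var_share`.
#' @export
pca_coords <- function(expr, n_components = 2) {
  if (ncol(expr) < 2) stopf("PCA needs at least two samples")
  x <- t(expr - rowMeans(expr))
  if (n_components > min(dim(x)))
    stopf("n_components exceeds the data dimension")
  sv <- svd(x, nu = n_components, nv = 0)
  coords <- sv$u * rep(sv$d[seq_len(n_components)], each = nrow(x))
  dimnames(coords) <- list(colnames(expr),
                           paste0("PC", seq_len(n_components)))
  tot <- sum(sv$d^2)
  list(coords = coords,
       var_share = if (tot > 0) sv$d[seq_len(n_components)]^2 / tot
                   else rep(0, n_components))
}
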