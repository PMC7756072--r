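#' Read an ortholog map
#'
#' Two-column TSV (`human_gene`, `zebrafish_gene`), possibly
#' many:many. Row order is preserved: it is the determinism source of
#' the first-match rule.
#'
#' @param path TSV path.
#' @return data.frame with columns `human_gene`, `zebrafish_gene`.
#' @export
read_orthomap <- function(path) {
  map <- read.delim(path, colClasses = "character")
  if (!all(c("human_gene", "zebrafish_gene") %in% names(map)))
    stopf("ortholog map needs human_gene and zebrafish_gene columns")
  if (any(!nzchar(map$human_gene)) || any(!nzchar(map$zebrafish_gene)))
    stopf("empty gene IDs in ortholog map")
  map <- map[!duplicated(map[, c("human_gene", "zebrafish_gene")]), ]
  rownames(map) <- NULL
  map
}

#' Map a term's genes across species
#'
#' `mode = "expand"`: the union of all ortholog images -- used for
#' set-level tests, where a gene with several orthologs contributes all
#' of them. `mode = "first"`: one deterministic partner per gene (first
#' matching map row, and at most one source per target) -- used for
#' fold-change heatmaps where rows must be unique. Unmapped genes are
#' dropped; their count is returned as the `dropped` attribute.
#'
#' @param genes character vector of gene IDs.
#' @param map ortholog map from [read_orthomap()] / [emit_orthomap()].
#' @param mode `"expand"` or `"first"`.
#' @param from `"human"` (map human to zebrafish) or `"zebrafish"`.
#' @return character vector of mapped IDs with attribute `dropped`.
#' @export
map_term_genes <- function(genes, map, mode = c("expand", "first"),
                           from = c("human", "zebrafish")) {
  mode <- match.arg(mode); from <- match.arg(from)
  if (!nrow(map)) stopf("empty ortholog map")
  src <- if (from == "human") map$human_gene else map$zebrafish_gene
  dst <- if (from == "human") map$zebrafish_gene else map$human_gene
  hit <- src %in% genes
  dropped <- sum(!genes %in% src)
  if (mode == "expand") {
    out <- unique(dst[hit])
  } else {
    sub_src <- src[hit]; sub_dst <- dst[hit]
    first <- !duplicated(sub_src)           # first map row per source gene
    out <- sub_dst[first]
    out <- out[!duplicated(out)]            # first source per target gene
  }
  structure(out, dropped = dropped)
}

#' Cross-condition concordance of term calls
#'
#' For every (cluster, condition) column pair of a significance matrix:
#' counts of concordant up/up and down/down term calls, discordant
#' calls (both called, opposite direction), and the agreement score
#' `matched / union of terms called in either column`. The score is
#' symmetric in the two call vectors and `NA` when neither column calls
#' any term.
#'
#' @param sig a [significance_matrix()].
#' @param cluster_cols,condition_cols column names to compare; default
#'   all-vs-all over the matrix columns.
#' @return data.frame `cluster`, `condition`, `up_up`, `down_down`,
#'   `discordant`, `agreement`.
#' @export
concordance <- function(sig, cluster_cols = colnames(sig),
                        condition_cols = colnames(sig)) {
  rows <- list()
  for (a in cluster_cols) for (b in condition_cols) {
    x <- sig[, a]; y <- sig[, b]
    called <- x != "ns" | y != "ns"
    upup <- sum(x == "up" & y == "up")
    dndn <- sum(x == "down" & y == "down")
    disc <- sum(x != "ns" & y != "ns" & x != y)
    rows[[length(rows) + 1]] <- data.frame(
      cluster = a, condition = b, up_up = upup, down_down = dndn,
      discordant = disc,
      agreement = if (sum(called)) (upup + dndn) / sum(called) else NA_real_)
  }
  do.call(rbind, rows)
}

#' Hierarchical clustering of a binary significance matrix
#'
#' Calls are encoded up = +1, down = -1, ns = 0 and rows and columns
#' are agglomeratively clustered on Euclidean distance; the returned
#' leaf orders drive heatmap rendering.
#'
#' @param sig a [significance_matrix()].
#' @param linkage agglomeration method (default `"complete"`).
#' @return list with `row_hclust`, `col_hclust` (`NULL` for single
#'   rows/columns), `row_order`, `col_order`, and the `encoded` matrix.
#' @export
hclust_binary <- function(sig, linkage = "complete") {
  num <- matrix(0, nrow(sig), ncol(sig), dimnames = dimnames(sig))
  num[sig == "up"] <- 1
  num[sig == "down"] <- -1
  cl <- function(m) if (nrow(m) > 1) hclust(dist(m), method = linkage) else NULL
  rh <- cl(num); ch <- cl(t(num))
  list(row_hclust = rh, col_hclust = ch,
       row_order = if (is.null(rh)) seq_len(nrow(num)) else rh$order,
       col_order = if (is.null(ch)) seq_len(ncol(num)) else ch$order,
       encoded = num)
}

#' Early-vs-late tumor-stage comparison
#'
#' Splits a cohort on the per-patient `stage` metadata (`early` =
#' stages I--II, `late` = III--IV), reruns the paired DE and the paired
#' gene-set statistic per stage group against the matched normals, and
#' compares the per-term `-log10 FDR` between stages after min--max
#' scaling each stage to \[0, 1\]. Stage groups with fewer than 3
#' complete pairs are skipped with a message.
#'
#' @param cm a paired-cohort [count_matrix()] whose metadata carries a
#'   `stage` column (`early`/`late` on tumor samples).
#' @param sets gene-set collection for [gage_paired()].
#' @param prior_count prior for [log_cpm()].
#' @return list with `table` (per-term `early`, `late` scaled values),
#'   `pearson_r`, `de` (per-stage `de_result`s), `skipped`.
#' @export
stage_split_compare <- function(cm, sets, prior_count = 0.5) {
  md <- cm$metadata
  if (is.null(md$stage)) stopf("metadata lacks a stage column")
  scaled <- list(); de_out <- list(); skipped <- character(0)
  for (stg in c("early", "late")) {
    pid <- unique(md$pair_id[md$condition == "tumor" & !is.na(md$stage) &
                               md$stage == stg])
    pid <- pid[pid %in% md$pair_id[md$condition == "normal"]]
    if (length(pid) < 3) {
      skipped <- c(skipped, stg)
      message(sprintf("stage '%s' skipped: fewer than 3 complete pairs", stg))
      next
    }
    keep <- md$sample_id[md$pair_id %in% pid]
    sub <- subset_samples(cm, keep)
    subf <- filter_low_expression(sub, min_samples = min(3, ncol(sub$counts)))
    fac <- tmm_factors(subf)
    expr <- log_cpm(subf, fac, prior_count)
    de_out[[stg]] <- paired_de(subf, fac)
    smd <- subf$metadata
    pr <- data.frame(
      tumor = smd$sample_id[match(pid, ifelse(smd$condition == "tumor", smd$pair_id, NA))],
      normal = smd$sample_id[match(pid, ifelse(smd$condition == "normal", smd$pair_id, NA))])
    gg <- gage_paired(expr, pr, sets)
    # strongest direction per term, then min-max scaled -log10 FDR
    gg <- gg[order(gg$term, gg$fdr), ]
    gg <- gg[!duplicated(gg$term), ]
    x <- -log10(pmax(gg$fdr, 1e-300))
    rng <- range(x)
    scaled[[stg]] <- stats::setNames(
      if (diff(rng) > 0) (x - rng[1]) / diff(rng) else rep(0, length(x)),
      gg$term)
  }
  if (length(scaled) < 2)
    return(list(table = NULL, pearson_r = NA_real_, de = de_out,
                skipped = skipped))
  terms <- intersect(names(scaled$early), names(scaled$late))
  tab <- data.frame(term = terms, early = scaled$early[terms],
                    late = scaled$late[terms], row.names = NULL)
  list(table = tab,
       pearson_r = if (nrow(tab) > 2) cor(tab$early, tab$late) else NA_real_,
       de = de_out, skipped = skipped)
}
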