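#' Read / filter a predicted miRNA-target table
#'
#' `read_targets` reads a TargetScan-like TSV with columns `mirna_id`,
#' `gene_id`, `context_score` (column aliases can be supplied).
#' `filter_targets` keeps predictions with a context score strictly
#' below `score_cut` (more negative = stronger predicted repression)
#' and de-duplicates (miRNA, gene) pairs keeping the most negative
#' score.
#'
#' @param path TSV path.
#' @param aliases optional named character vector mapping file columns
#'   to the canonical names, e.g. `c(miRNA = "mirna_id")`.
#' @param table data.frame with the three canonical columns.
#' @param score_cut keep rows with `context_score < score_cut`.
#' @export
read_targets <- function(path, aliases = NULL) {
  df <- read.delim(path)
  if (!is.null(aliases))
    names(df)[match(names(aliases), names(df))] <- aliases
  need <- c("mirna_id", "gene_id", "context_score")
  if (!all(need %in% names(df)))
    stopf("target table needs columns: %s", paste(need, collapse = ", "))
  df[need]
}

#' @rdname read_targets
#' @export
filter_targets <- function(table, score_cut = -0.2) {
  need <- c("mirna_id", "gene_id", "context_score")
  if (!all(need %in% names(table)))
    stopf("target table needs columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(table$context_score)))
    stopf("context scores must be finite")
  out <- table[table$context_score < score_cut, need, drop = FALSE]
  out <- out[order(out$mirna_id, out$gene_id, out$context_score), ]
  out <- out[!duplicated(out[, c("mirna_id", "gene_id")]), ]
  rownames(out) <- NULL
  out
}

#' Anticorrelation screen over predicted miRNA--mRNA pairs
#'
#' For each candidate pair, the Pearson correlation of miRNA and mRNA
#' expression across the shared samples, restricted to significantly
#' regulated molecules of opposite direction (the two direction splits
#' `miR-up/mRNA-down` and `miR-down/mRNA-up` are analyzed separately).
#' FDR is Benjamini--Hochberg across the tested pairs within each
#' direction split; an interaction is valid when `rho < -0.4` and
#' `FDR < 0.05`.
#'
#' @param mrna_expr,mirna_expr expression matrices sharing >= 5 sample
#'   columns (for cohorts: the samples of patients paired for both
#'   molecule types).
#' @param candidates filtered target table ([filter_targets()]).
#' @param mrna_calls,mirna_calls named call vectors (`up`/`down`/`ns`,
#'   names = IDs), e.g. the `call` column of a `de_result`. When both
#'   are `NULL` every candidate pair measured in both matrices is
#'   tested in a single `"all"` split (useful for planted-truth
#'   checks).
#' @param rho_cut,fdr_cut validity thresholds.
#' @return an `interaction_result` data.frame: `mirna`, `gene`, `rho`,
#'   `p`, `fdr`, `valid`, `direction`; attribute `skipped` counts
#'   zero-variance pairs.
#' @export
correlate_pairs <- function(mrna_expr, mirna_expr, candidates,
                            mrna_calls = NULL, mirna_calls = NULL,
                            rho_cut = -0.4, fdr_cut = 0.05) {
  shared <- intersect(colnames(mrna_expr), colnames(mirna_expr))
  if (length(shared) < 5) stopf("need at least 5 shared samples")
  mrna_expr <- mrna_expr[, shared, drop = FALSE]
  mirna_expr <- mirna_expr[, shared, drop = FALSE]
  cand <- candidates[candidates$gene_id %in% rownames(mrna_expr) &
                       candidates$mirna_id %in% rownames(mirna_expr), ]
  if (is.null(mrna_calls) && is.null(mirna_calls)) {
    cand$direction <- "all"
  } else {
    if (is.null(mrna_calls) || is.null(mirna_calls))
      stopf("supply both call vectors or neither")
    mdir <- mirna_calls[cand$mirna_id]
    gdir <- mrna_calls[cand$gene_id]
    cand$direction <- ifelse(mdir == "up" & gdir == "down", "miR-up/mRNA-down",
                      ifelse(mdir == "down" & gdir == "up", "miR-down/mRNA-up",
                             NA_character_))
    cand <- cand[!is.na(cand$direction), ]
  }
  n <- length(shared)
  skipped <- 0L
  rho <- p <- rep(NA_real_, nrow(cand))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    x <- mirna_expr[cand$mirna_id[i], ]
    y <- mrna_expr[cand$gene_id[i], ]
    if (sd(x) < 1e-12 || sd(y) < 1e-12) { skipped <- skipped + 1L; next }
    r <- cor(x, y)
    tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
    rho[i] <- r
    p[i] <- 2 * pt(-abs(tt), n - 2)
    keep[i] <- TRUE
  }
  if (skipped)
    message(sprintf("%d pair(s) skipped for zero variance", skipped))
  out <- data.frame(mirna = cand$mirna_id, gene = cand$gene_id,
                    rho = rho, p = p, fdr = NA_real_,
                    valid = FALSE, direction = cand$direction)[keep, , drop = FALSE]
  for (d in unique(out$direction))
    out$fdr[out$direction == d] <- bh_fdr(out$p[out$direction == d])
  out$valid <- out$rho < rho_cut & out$fdr < fdr_cut
  rownames(out) <- NULL
  structure(out, class = c("interaction_result", "data.frame"),
            skipped = skipped)
}

#' Merge miRNAs sharing targets; rank groups; enrich targets
#'
#' `merge_mirnas`: for every pair of miRNAs with valid interactions,
#' the hypergeometric upper-tail probability of their valid-target
#' overlap within the universe of tested mRNAs; pairs with
#' `FDR < overlap_fdr` become edges and the connected components are
#' the merged groups (singletons are their own group). `top_k_groups`
#' ranks groups by the size of their union target set (ties: more
#' members, then lexicographic lead miRNA) and truncates to `k`.
#' `enrich_targets` runs [ora_fisher()] on each group's union target
#' set; terms are significant at nominal `p < p_cut`.
#'
#' @param interactions an `interaction_result`.
#' @param universe character vector of tested mRNAs (the hypergeometric
#'   universe).
#' @param overlap_fdr merge threshold.
#' @return `merge_mirnas`: list of groups, each
#'   `list(members, targets, member_targets)`.
#' @export
merge_mirnas <- function(interactions, universe, overlap_fdr = 0.01) {
  val <- interactions[interactions$valid, , drop = FALSE]
  tsets <- lapply(split(val$gene, val$mirna), unique)
  mirs <- names(tsets)
  N <- length(unique(universe))
  if (length(mirs) > 1) {
    pairs <- utils::combn(mirs, 2)
    pv <- apply(pairs, 2, function(pr) {
      a <- tsets[[pr[1]]]; b <- tsets[[pr[2]]]
      k <- length(intersect(a, b))
      phyper(k - 1, length(a), N - length(a), length(b), lower.tail = FALSE)
    })
    fdr <- bh_fdr(pv)
    edge <- pairs[, fdr < overlap_fdr, drop = FALSE]
  } else {
    edge <- matrix(character(0), 2, 0)
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(mirs), name = mirs)
  if (ncol(edge))
    g <- igraph::add_edges(g, match(as.vector(edge), mirs))
  comp <- igraph::components(g)$membership
  lapply(split(mirs, comp), function(members) {
    list(members = sort(members),
         targets = sort(unique(unlist(tsets[members]))),
         member_targets = lengths(tsets[members]))
  })
}

#' @rdname merge_mirnas
#' @param groups output of [merge_mirnas()].
#' @param k number of groups to keep.
#' @export
top_k_groups <- function(groups, k = 15) {
  if (!length(groups)) return(groups)
  lead <- vapply(groups, function(g) g$members[1], character(1))
  ord <- order(-lengths(lapply(groups, `[[`, "targets")),
               -lengths(lapply(groups, `[[`, "members")),
               lead)
  out <- groups[ord][seq_len(min(k, length(groups)))]
  names(out) <- vapply(out, function(g) g$members[1], character(1))
  out
}

#' @rdname merge_mirnas
#' @param sets gene-set collection.
#' @param p_cut nominal significance threshold for target enrichment.
#' @export
enrich_targets <- function(groups, sets, universe, p_cut = 0.01) {
  rows <- list()
  for (nm in names(groups)) {
    tg <- intersect(groups[[nm]]$targets, universe)
    if (!length(tg)) { message(sprintf("group %s skipped: empty target set", nm)); next }
    res <- ora_fisher(tg, sets, universe)
    res$group <- nm
    res$significant <- res$p < p_cut
    rows[[nm]] <- res
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
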