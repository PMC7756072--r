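#' Read / write GMT gene-set collections
#'
#' Standard GMT lines: set name, description, then tab-separated gene
#' IDs. `read_gmt` returns a named list with a `description` attribute;
#' `write_gmt` is its inverse (round-trip identity).
#'
#' @param path file path.
#' @param sets named list of character vectors (names unique, sets
#'   non-empty).
#' @param descriptions optional per-set description column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stopf("duplicate set names in %s", path)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("sets must carry unique names")
  if (any(lengths(sets) == 0)) stopf("empty gene sets cannot be written")
  descriptions <- descriptions %||% rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' One-sided Fisher over-representation test
#'
#' For each term, the hypergeometric upper-tail probability of the
#' observed overlap between the query and the term's genes within the
#' universe (identical to the one-sided Fisher exact enrichment test on
#' the 2x2 table). Sets are intersected with the universe before
#' testing; FDR is Benjamini--Hochberg across terms.
#'
#' @param query character vector of gene IDs, a subset of `universe`.
#' @param sets named list of gene vectors (a GMT collection).
#' @param universe character vector of tested genes.
#' @return an `enrichment_result` data.frame: `term`, `p`, `fdr`,
#'   `overlap`, `set_size`, `query_size`, `gene_ratio`, `direction`.
#' @export
ora_fisher <- function(query, sets, universe) {
  if (!length(universe)) stopf("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  bad <- setdiff(query, universe)
  if (length(bad))
    stopf("query genes outside the universe: %s%s",
          paste(head(bad, 5), collapse = ", "),
          if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else "")
  N <- length(universe); q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(query, s))
    data.frame(term = nm,
               p = phyper(k - 1, length(s), N - length(s), q, lower.tail = FALSE),
               overlap = k, set_size = length(s), query_size = q,
               gene_ratio = if (length(s)) k / length(s) else 0)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$direction <- "n/a"
  out <- out[, c("term", "p", "fdr", "overlap", "set_size", "query_size",
                 "gene_ratio", "direction")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Paired gene-set statistic (gage-style, Stouffer-combined)
#'
#' Per pair, per-gene log2 ratios (tumor minus normal log-CPM); per
#' pair and per set, a two-sample unequal-variance t of the set genes'
#' ratios against all genes' ratios, one-sided for each direction; the
#' per-pair p-values are combined across pairs by Stouffer's method and
#' FDR-adjusted per direction. A set is reported `up` when the up test
#' passes the cutoff downstream, `down` for the down test.
#'
#' @param expr log-expression matrix (genes x samples), e.g.
#'   [log_cpm()].
#' @param pairs data.frame with columns `tumor` and `normal` holding
#'   sample IDs (>= 2 complete pairs).
#' @param sets named list of gene vectors.
#' @param min_set minimum measured genes per set; smaller sets are
#'   skipped with a message.
#' @return an `enrichment_result` data.frame with one row per (term,
#'   direction): `term`, `direction`, `p`, `fdr`, `set_size`,
#'   `mean_stat` (mean per-pair t).
#' @export
gage_paired <- function(expr, pairs, sets, min_set = 2) {
  if (nrow(pairs) < 2) stopf("need at least 2 complete pairs")
  if (!all(c(pairs$tumor, pairs$normal) %in% colnames(expr)))
    stopf("pair sample IDs missing from the expression matrix")
  ratio <- expr[, pairs$tumor, drop = FALSE] - expr[, pairs$normal, drop = FALSE]
  k <- ncol(ratio)
  measured <- rownames(expr)
  skipped <- character(0)
  rows <- list()
  for (nm in names(sets)) {
    idx <- which(measured %in% sets[[nm]])
    if (length(idx) < min_set) { skipped <- c(skipped, nm); next }
    t_pair <- p_up <- numeric(k)
    for (j in seq_len(k)) {
      x <- ratio[idx, j]; y <- ratio[, j]
      v <- var(x) / length(x) + var(y) / length(y)
      t_j <- (mean(x) - mean(y)) / sqrt(v)
      df <- v^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                     (var(y) / length(y))^2 / (length(y) - 1))
      t_pair[j] <- t_j
      p_up[j] <- pt(t_j, df, lower.tail = FALSE)
    }
    comb <- function(pv) {
      z <- qnorm(pmin(pmax(pv, 1e-15), 1 - 1e-15), lower.tail = FALSE)
      pnorm(sum(z) / sqrt(k), lower.tail = FALSE)
    }
    rows[[nm]] <- data.frame(
      term = nm, direction = c("up", "down"),
      p = c(comb(p_up), comb(1 - p_up)),
      set_size = length(idx), mean_stat = mean(t_pair))
  }
  if (length(skipped))
    message(sprintf("%d set(s) skipped (fewer than %d measured genes): %s",
                    length(skipped), min_set,
                    paste(head(skipped, 3), collapse = ", ")))
  if (!length(rows))
    return(structure(data.frame(term = character(), direction = character(),
                                p = numeric(), fdr = numeric(),
                                set_size = integer(), mean_stat = numeric()),
                     class = c("enrichment_result", "data.frame")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- NA_real_
  for (d in c("up", "down"))
    out$fdr[out$direction == d] <- bh_fdr(out$p[out$direction == d])
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Term-by-condition significance matrix
#'
#' Collapses enrichment results from several conditions into the
#' categorical matrix used by all cross-condition heatmaps and the
#' concordance analysis: each cell is `up`, `down` or `ns` after
#' applying the per-source cutoff (clusters FDR < 0.1, cohorts
#' FDR < 0.01, miRNA target enrichment p < 0.01).
#'
#' @param results data.frame with columns `term`, `condition`,
#'   `direction` (`up`/`down`/`n/a`), `p`, `fdr` (e.g. row-bound
#'   [ora_fisher()]/[gage_paired()] outputs with a `condition` column
#'   added). Over-representation sources have no intrinsic direction;
#'   assign one upstream (e.g. a cluster's trajectory direction) --
#'   significant rows still tagged `n/a` are recorded as `up`.
#' @param cutoffs named list, one entry per condition:
#'   `list(stat = "fdr"|"p", cut = <threshold>)`.
#' @return character matrix terms x conditions over `{up, down, ns}`,
#'   class `significance_matrix`.
#' @export
significance_matrix <- function(results, cutoffs) {
  need <- c("term", "condition", "direction", "p")
  if (!all(need %in% names(results)))
    stopf("results need columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(results[, c("term", "condition", "direction")]))
    stopf("conflicting duplicate (term, condition, direction) entries")
  conds <- unique(results$condition)
  missing_cut <- setdiff(conds, names(cutoffs))
  if (length(missing_cut))
    stopf("no cutoff for condition(s): %s", paste(missing_cut, collapse = ", "))
  terms <- sort(unique(results$term))
  out <- matrix("ns", length(terms), length(conds),
                dimnames = list(terms, conds))
  for (cond in conds) {
    cut <- cutoffs[[cond]]
    sub <- results[results$condition == cond, ]
    stat <- if (identical(cut$stat, "p")) sub$p else sub$fdr
    sig <- sub[stat < cut$cut & sub$direction %in% c("up", "down", "n/a"), ]
    if (!nrow(sig)) next
    # if both directions pass for one term, keep the stronger one
    sig <- sig[order(sig$p), ]
    sig <- sig[!duplicated(sig$term), ]
    dir <- ifelse(sig$direction == "n/a", "up", sig$direction)
    out[cbind(match(sig$term, terms), match(cond, conds))] <- dir
  }
  structure(out, class = c("significance_matrix", class(out)))
}
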