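#' De-duplicate near-identical terms
#'
#' Terms are visited in increasing p order (ties: larger gene set, then
#' lexicographic name); a term is discarded when its sharing fraction
#' with any already-retained term exceeds `share_cut`. The sharing
#' fraction is `|A intersect B| / min(|A|, |B|)` -- the min-set
#' convention, under which near-duplicates and subset-terms are
#' actually removed.
#'
#' @param terms data.frame with columns `term`, `p`, and a list-column
#'   `genes`.
#' @param share_cut sharing fraction above which (strict `>`) a term is
#'   discarded.
#' @return the retained subset of `terms`, in keep order.
#' @export
dedupe_terms <- function(terms, share_cut = 0.98) {
  if (!nrow(terms)) return(terms)
  ord <- order(terms$p, -lengths(terms$genes), terms$term)
  terms <- terms[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(terms))) {
    gi <- terms$genes[[i]]
    dup <- any(vapply(kept, function(j) {
      gj <- terms$genes[[j]]
      length(intersect(gi, gj)) / min(length(gi), length(gj)) > share_cut
    }, logical(1)))
    if (!dup) kept <- c(kept, i)
  }
  out <- terms[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

share_fraction <- function(a, b) length(intersect(a, b)) / min(length(a), length(b))

#' Cluster--term network from enrichment results
#'
#' Builds the graph used to survey a cluster's functional landscape:
#' per cluster the significant terms are de-duplicated
#' ([dedupe_terms()]), then term--term edges connect terms sharing more
#' than `edge_cut` (strict) of their genes (weight = sharing fraction),
#' and each term attaches to every cluster in which it is significant
#' with weight `-log10 p`. Node size is `-log10 p` (max over clusters),
#' i.e. anticorrelated with the p-value.
#'
#' @param cluster_terms named list (one entry per cluster) of
#'   data.frames with columns `term`, `p`, list-column `genes`.
#' @param edge_cut sharing fraction above which terms are connected.
#' @param share_cut dedup threshold passed to [dedupe_terms()].
#' @return an igraph graph; term nodes carry `p`, `size`, cluster
#'   anchor nodes carry `type = "cluster"`; edges carry `weight`.
#' @export
build_network <- function(cluster_terms, edge_cut = 0.4, share_cut = 0.98) {
  deduped <- lapply(cluster_terms, dedupe_terms, share_cut = share_cut)
  all_terms <- list(); term_p <- list()
  for (cl in names(deduped)) {
    d <- deduped[[cl]]
    for (i in seq_len(nrow(d))) {
      nm <- d$term[i]
      all_terms[[nm]] <- d$genes[[i]]
      term_p[[nm]] <- min(term_p[[nm]] %||% Inf, d$p[i])
    }
  }
  terms <- names(all_terms)
  edges <- character(0); weights <- numeric(0)
  if (length(terms) > 1) {
    for (i in seq_along(terms)[-length(terms)]) {
      for (j in (i + 1):length(terms)) {
        s <- share_fraction(all_terms[[terms[i]]], all_terms[[terms[j]]])
        if (s > edge_cut) {
          edges <- c(edges, terms[i], terms[j])
          weights <- c(weights, s)
        }
      }
    }
  }
  for (cl in names(deduped)) {
    d <- deduped[[cl]]
    for (i in seq_len(nrow(d))) {
      edges <- c(edges, cl, d$term[i])
      weights <- c(weights, -log10(max(d$p[i], 1e-300)))
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(names(deduped)),
                            name = names(deduped), type = "cluster",
                            p = NA_real_, size_attr = NA_real_)
  g <- igraph::add_vertices(g, length(terms), name = terms, type = "term",
                            p = unlist(term_p[terms]) %||% numeric(0),
                            size_attr = -log10(pmax(unlist(term_p[terms]), 1e-300)))
  if (length(edges))
    g <- igraph::add_edges(g, match(edges, igraph::V(g)$name),
                           weight = weights)
  g
}

#' Export a term network
#'
#' Writes GraphML (via igraph) and a minimal GEXF 1.2 document with the
#' node attributes (`type`, `p`, `size_attr`) and edge weights, for
#' layout in external viewers.
#'
#' @param g graph from [build_network()].
#' @param graphml_path,gexf_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
export_term_network <- function(g, graphml_path = NULL, gexf_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(gexf_path)) {
    v <- igraph::as_data_frame(g, "vertices")
    e <- igraph::as_data_frame(g, "edges")
    esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", as.character(x)))
    nodes <- sprintf('      <node id="%s" label="%s"><attvalues><attvalue for="0" value="%s"/><attvalue for="1" value="%s"/></attvalues></node>',
                     esc(v$name), esc(v$name), esc(v$type), esc(v$size_attr))
    edges <- if (nrow(e))
      sprintf('      <edge id="%d" source="%s" target="%s" weight="%s"/>',
              seq_len(nrow(e)) - 1L, esc(e$from), esc(e$to), esc(e$weight))
    else character(0)
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
      '  <graph defaultedgetype="undirected">',
      '    <attributes class="node">',
      '      <attribute id="0" title="type" type="string"/>',
      '      <attribute id="1" title="size" type="double"/>',
      '    </attributes>',
      '    <nodes>', nodes, '    </nodes>',
      '    <edges>', edges, '    </edges>',
      '  </graph>', '</gexf>'), gexf_path)
  }
  invisible(c(graphml_path, gexf_path))
}
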