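#' Benjamini--Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone enforced, capped at 1), via
#' `stats::p.adjust`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p))) stopf("NaN/NA p-values are not admissible")
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Negative-binomial dispersion: raw, trended, tagwise
#'
#' Raw per-gene dispersion by method of moments on library-size-adjusted
#' counts within replicate groups (`phi = max(0, (s^2 - mu)/mu^2)`),
#' a mean--dispersion trend by local regression of the raw values on the
#' mean, and a tagwise (shrunk) value as an empirical-Bayes weighted
#' combination of raw and trend with weight
#' `prior_df / (prior_df + residual_df)`. The shrunk value always lies
#' between raw and trend. This fit parallels the tagwise-dispersion step
#' of count-based DE engines; the pipeline's own tests are
#' moderated-t on log-CPM, and the fit is exposed for NB-GLM extensions.
#'
#' @param cm a [count_matrix()].
#' @param factors matching [tmm_factors()] output.
#' @param design factor/character grouping samples into replicate groups.
#' @param prior_df prior degrees of freedom for the shrinkage.
#' @return data.frame `gene_id`, `mean`, `raw`, `trend`, `tagwise`,
#'   `weight` with class `dispersion_fit`.
#' @export
estimate_dispersion <- function(cm, factors, design, prior_df = 10) {
  design <- as.factor(design)
  if (length(design) != ncol(cm$counts))
    stopf("design length must match the number of samples")
  nrep <- table(design)
  if (all(nrep < 2)) stopf("all groups are singletons; no replication")
  eff <- factors$effective_lib_size
  y <- t(t(cm$counts) / eff) * exp(mean(log(eff)))  # pseudo-counts
  groups <- levels(design)[nrep >= 2]
  ssq <- mu_num <- 0
  df_resid <- 0
  for (g in groups) {
    idx <- which(design == g)
    m <- rowMeans(y[, idx, drop = FALSE])
    v <- apply(y[, idx, drop = FALSE], 1, var)
    ssq <- ssq + (length(idx) - 1) * v
    mu_num <- mu_num + length(idx) * m
    df_resid <- df_resid + length(idx) - 1
  }
  s2 <- ssq / df_resid
  mu <- mu_num / sum(nrep[nrep >= 2])
  raw <- pmax(0, (s2 - mu) / mu^2)
  trend <- if (length(unique(mu)) < 5) {
    rep(mean(raw), length(raw))  # too few distinct means for a trend
  } else {
    lo <- lowess(log(mu), raw, f = 0.5)
    pmax(approx(lo$x, lo$y, xout = log(mu), rule = 2)$y, 0)
  }
  w <- prior_df / (prior_df + df_resid)
  tagwise <- w * trend + (1 - w) * raw
  structure(data.frame(gene_id = rownames(cm$counts), mean = mu, raw = raw,
                       trend = trend, tagwise = tagwise, weight = w,
                       row.names = NULL),
            class = c("dispersion_fit", "data.frame"))
}

#' Paired differential expression (moderated paired t on log-CPM)
#'
#' Per pair, the tumor minus normal log2-CPM difference; per gene, a
#' one-sample moderated location test across pairs. The gene-wise
#' variances are squeezed toward their median with a fixed prior
#' `prior_df` (empirical-Bayes moderation); log2FC is the mean paired
#' difference; FDR is Benjamini--Hochberg over all tested genes. The
#' paired design removes between-patient heterogeneity.
#'
#' @param cm a [count_matrix()] whose metadata carries `pair_id` and
#'   conditions `tumor`/`normal` (at least 3 complete pairs).
#' @param factors matching [tmm_factors()] output.
#' @param prior_df prior degrees of freedom of the variance shrinkage.
#' @param prior_count prior for [log_cpm()].
#' @return a `de_result` data.frame: `gene_id`, `log2FC`, `raw_p`,
#'   `fdr`, `call` (all `"ns"` until [call_degs()] is applied).
#' @export
paired_de <- function(cm, factors, prior_df = 4, prior_count = 0.5) {
  md <- cm$metadata
  pairs <- intersect(md$pair_id[md$condition == "tumor"],
                     md$pair_id[md$condition == "normal"])
  pairs <- pairs[!is.na(pairs)]
  if (length(pairs) < 3) stopf("need at least 3 complete tumor-normal pairs")
  expr <- log_cpm(cm, factors, prior_count)
  t_idx <- md$sample_id[match(pairs, ifelse(md$condition == "tumor", md$pair_id, NA))]
  n_idx <- md$sample_id[match(pairs, ifelse(md$condition == "normal", md$pair_id, NA))]
  d <- expr[, t_idx, drop = FALSE] - expr[, n_idx, drop = FALSE]
  n <- length(pairs)
  delta <- rowMeans(d)
  s2 <- apply(d, 1, var)
  s2_post <- squeeze_var(s2, n - 1, prior_df)
  se <- sqrt(s2_post / n)
  p <- moderated_p(delta, se, df = prior_df + n - 1)
  de_result(rownames(cm$counts), delta, p)
}

de_result <- function(gene_id, log2FC, raw_p) {
  structure(data.frame(gene_id = gene_id, log2FC = log2FC, raw_p = raw_p,
                       fdr = bh_fdr(raw_p), call = "ns",
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"),
            thresholds = NULL, relaxation_applied = FALSE)
}

#' Call differentially expressed genes, with the small-yield relaxation
#'
#' A gene is `up` if `fdr < fdr_cut` and `log2FC > lfc_cut`, `down` if
#' `fdr < fdr_cut` and `log2FC < -lfc_cut`, otherwise `ns`. If the
#' resulting up-count or down-count is below `relax_min`, calls are
#' recomputed at the relaxed FDR threshold `relax_fdr` and the
#' `relaxation_applied` attribute is set.
#'
#' @param de a `de_result` (from [paired_de()] or built by hand).
#' @param fdr_cut,lfc_cut primary thresholds.
#' @param relax_fdr relaxed FDR threshold.
#' @param relax_min minimum per-direction yield before relaxing.
#' @return the `de_result` with `call` filled in and attributes
#'   `thresholds` and `relaxation_applied`.
#' @export
call_degs <- function(de, fdr_cut = 0.01, lfc_cut = 1,
                      relax_fdr = 0.05, relax_min = 50) {
  apply_cut <- function(cut) {
    call <- rep("ns", nrow(de))
    call[de$fdr < cut & de$log2FC > lfc_cut] <- "up"
    call[de$fdr < cut & de$log2FC < -lfc_cut] <- "down"
    call
  }
  call <- apply_cut(fdr_cut)
  relaxed <- FALSE
  if (sum(call == "up") < relax_min || sum(call == "down") < relax_min) {
    call <- apply_cut(relax_fdr)
    relaxed <- TRUE
  }
  de$call <- call
  attr(de, "thresholds") <- list(fdr_cut = if (relaxed) relax_fdr else fdr_cut,
                                 lfc_cut = lfc_cut)
  attr(de, "relaxation_applied") <- relaxed
  de
}

#' Write a DE result table as TSV
#'
#' Columns `gene_id`, `log2FC`, `raw_p`, `fdr`, `call`.
#'
#' @param de a `de_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_de_result <- function(de, path) {
  write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
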