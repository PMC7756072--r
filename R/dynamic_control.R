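#' Time-dependent control weights
#'
#' The modeled control blends sham-operated and healthy fish with a
#' sham weight that decays exponentially with time after injury:
#' `w(t) = exp(-t / tau)`, healthy weight `1 - w(t)`. At t = 0 the
#' control is pure sham; the surgery's influence vanishes as the time
#' course progresses and late timepoints are compared against healthy
#' hearts.
#'
#' @param timepoints days post injury (non-negative).
#' @param tau decay timescale in days (> 0); the default 7 puts the
#'   sham influence below 2% by 30 dpi.
#' @return an object of class `control_model`: data.frame `timepoint`,
#'   `sham_weight`, `healthy_weight`, with attribute `tau`.
#' @export
control_weights <- function(timepoints, tau = 7) {
  if (tau <= 0) stopf("tau must be positive")
  if (any(timepoints < 0)) stopf("timepoints must be non-negative")
  w <- exp(-timepoints / tau)
  structure(data.frame(timepoint = timepoints, sham_weight = w,
                       healthy_weight = 1 - w),
            class = c("control_model", "data.frame"), tau = tau)
}

#' Per-timepoint differential expression against the modeled control
#'
#' For each timepoint t: the control mean log-CPM is
#' `w(t) * mean(sham at t) + (1 - w(t)) * mean(healthy)`; log2FC is the
#' injured mean minus that blend. Significance comes from a moderated
#' test in which control replicates enter with observation weights
#' `w(t)/n_sham` and `(1 - w(t))/n_healthy`: the standard error uses
#' the pooled within-group variance (groups with zero weight excluded,
#' so the `tau -> 0` limit reproduces injured-vs-healthy exactly),
#' empirical-Bayes squeezed across genes, and FDR is Benjamini--Hochberg
#' per timepoint.
#'
#' @param cm a [count_matrix()] with injured/sham/healthy metadata.
#' @param factors matching [tmm_factors()] output.
#' @param model a [control_weights()] model covering the injured
#'   timepoints.
#' @param prior_df prior degrees of freedom of the variance shrinkage.
#' @param prior_count prior for [log_cpm()].
#' @param fallback if `TRUE`, a timepoint without sham samples
#'   renormalizes the control onto healthy fish (with a message);
#'   otherwise it is an error while the sham weight is non-negligible.
#' @return an object of class `trajectory_matrix`: list with `log2FC`,
#'   `p`, `fdr` (gene x timepoint matrices, columns in grid order) and
#'   `model`.
#' @export
timecourse_de <- function(cm, factors, model, prior_df = 4,
                          prior_count = 0.5, fallback = TRUE) {
  md <- cm$metadata
  tps <- sort(unique(md$timepoint[md$condition == "injured"]))
  if (!length(tps)) stopf("no injured samples in the metadata")
  if (!all(tps %in% model$timepoint))
    stopf("control model does not cover all injured timepoints")
  expr <- log_cpm(cm, factors, prior_count)
  healthy <- md$sample_id[md$condition == "healthy"]
  if (!length(healthy)) stopf("no healthy samples in the metadata")

  lfc <- p <- matrix(NA_real_, nrow(expr), length(tps),
                     dimnames = list(rownames(expr), as.character(tps)))
  for (i in seq_along(tps)) {
    t <- tps[i]
    w <- model$sham_weight[match(t, model$timepoint)]
    inj <- md$sample_id[md$condition == "injured" & md$timepoint == t]
    sham <- md$sample_id[md$condition == "sham" & !is.na(md$timepoint) &
                           md$timepoint == t]
    if (!length(sham)) {
      if (w > 1e-12 && !fallback)
        stopf("no sham samples at %g dpi while sham weight is %.3g", t, w)
      if (w > 1e-12)
        message(sprintf("timepoint %g dpi: no sham samples, control renormalized onto healthy", t))
      w <- 0
    }
    n1 <- length(inj)
    m1 <- rowMeans(expr[, inj, drop = FALSE])
    m_sham <- if (length(sham)) rowMeans(expr[, sham, drop = FALSE]) else 0
    m_heal <- rowMeans(expr[, healthy, drop = FALSE])
    lfc[, i] <- m1 - (w * m_sham + (1 - w) * m_heal)

    # pooled within-group variance over groups that actually contribute
    groups <- list(inj)
    v_wt_sq <- 1 / n1  # injured replicates enter with unit weight
    sum_v2 <- 0
    if (w > 0) {
      groups <- c(groups, list(sham))
      sum_v2 <- sum_v2 + length(sham) * (w / length(sham))^2
    }
    if (w < 1) {
      groups <- c(groups, list(healthy))
      sum_v2 <- sum_v2 + length(healthy) * ((1 - w) / length(healthy))^2
    }
    ssq <- 0; df_resid <- 0
    for (g in groups) {
      if (length(g) < 2) next
      ssq <- ssq + (length(g) - 1) * apply(expr[, g, drop = FALSE], 1, var)
      df_resid <- df_resid + length(g) - 1
    }
    if (df_resid == 0) stopf("no replicated group at %g dpi", t)
    s2_post <- squeeze_var(ssq / df_resid, df_resid, prior_df)
    se <- sqrt(s2_post * (v_wt_sq + sum_v2))
    p[, i] <- moderated_p(lfc[, i], se, df = prior_df + df_resid)
  }
  fdr <- apply(p, 2, bh_fdr)
  structure(list(log2FC = lfc, p = p, fdr = fdr, model = model),
            class = "trajectory_matrix")
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf("trajectory_matrix: %d genes x %d timepoints (tau = %g)\n",
              nrow(x$log2FC), ncol(x$log2FC), attr(x$model, "tau")))
  invisible(x)
}

#' Union of per-timepoint DEG sets
#'
#' Genes significant at at least one timepoint under the stated cuts
#' (`fdr < fdr_cut` and `|log2FC| > lfc_cut`); this union feeds the
#' trajectory soft clustering.
#'
#' @param traj a [timecourse_de()] result.
#' @param fdr_cut,lfc_cut DEG thresholds.
#' @return character vector of gene IDs.
#' @export
union_degs <- function(traj, fdr_cut = 0.01, lfc_cut = 1) {
  hit <- traj$fdr < fdr_cut & abs(traj$log2FC) > lfc_cut
  rownames(traj$log2FC)[rowSums(hit, na.rm = TRUE) > 0]
}
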