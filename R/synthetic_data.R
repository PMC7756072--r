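#' Default trajectory archetypes
#'
#' Five log2 fold-change motifs on the injury time grid, in effect-size
#' units (peak magnitude 1, scaled by `effect_size` at simulation time).
#' The motifs represent the canonical dynamics of a regenerative response
#' while differing in peak timing, because per-gene z-scoring (the input
#' to soft clustering) removes level and scale and can only separate
#' shapes that differ in phase:
#' \describe{
#'   \item{induced.early}{up, peak 4--7 dpi, resolved by 45 dpi}
#'   \item{repressed.early}{down, trough 4--7 dpi, resolved by 45 dpi}
#'   \item{induced.mid}{up, peak 14--21 dpi, mildly below baseline late}
#'   \item{repressed.mid}{down, trough 14--21 dpi, mildly above late}
#'   \item{induced.late}{slow rise, plateau from 120 dpi}
#' }
#'
#' @param timepoints time grid in days; curves are interpolated onto it.
#' @return matrix archetypes x timepoints, rownames are motif names.
#' @export
default_archetypes <- function(timepoints = c(1, 4, 7, 14, 21, 30, 45, 60, 120, 160)) {
  base_t <- c(1, 4, 7, 14, 21, 30, 45, 60, 120, 160)
  shapes <- rbind(
    induced.early   = c(0.7, 1, 1, 0.6, 0.3, 0.1, 0, 0, 0, 0),
    repressed.early = -c(0.7, 1, 1, 0.6, 0.3, 0.1, 0, 0, 0, 0),
    induced.mid     = c(0, 0.3, 0.6, 1, 0.9, 0.5, 0.1, -0.1, -0.2, -0.2),
    repressed.mid   = -c(0, 0.3, 0.6, 1, 0.9, 0.5, 0.1, -0.1, -0.2, -0.2),
    induced.late    = c(0, 0, 0.05, 0.1, 0.2, 0.35, 0.6, 0.8, 1, 1)
  )
  out <- t(apply(shapes, 1, function(y)
    approx(base_t, y, xout = timepoints, rule = 2)$y))
  colnames(out) <- as.character(timepoints)
  out
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: the injury time course
#' (10 timepoints, 1--160 days post injury, injured + sham fish per
#' timepoint plus healthy controls) and the paired tumor--normal cohort
#' with a repressive miRNA block and planted gene-set signal. The same
#' seed always reproduces bit-identical data; all sub-generators derive
#' their streams from it.
#'
#' @param seed integer master seed.
#' @param n_genes number of genes in the universe.
#' @param timepoints strictly increasing days post injury.
#' @param n_injured_per_tp,n_sham_per_tp injured and sham replicates per
#'   timepoint.
#' @param n_healthy number of healthy control fish (pooled across ages).
#' @param n_pairs patients with paired tumor and normal samples.
#' @param archetype_curves matrix of per-cluster trajectory shapes
#'   (archetypes x timepoints, effect-size units).
#' @param frac_de fraction of genes planted on a trajectory archetype.
#' @param frac_de_tumor fraction of genes planted as tumor DE.
#' @param tumor_overlap probability that an archetype gene is also
#'   planted in the tumor cohort (same direction as its peak).
#' @param effect_size planted |log2FC| at the archetype peak and for
#'   tumor genes.
#' @param sham_scale amplitude of the transient surgery effect relative
#'   to the injury effect (< 1).
#' @param sham_end day by which the sham effect has decayed to zero.
#' @param baseline_meanlog,baseline_sdlog lognormal baseline means.
#' @param dispersion list: `phi0` (asymptotic NB dispersion, BCV^2),
#'   `phi_scale` (1/mu term) and `sdlog` (lognormal gene scatter), giving
#'   variance mu + phi mu^2 with phi = (phi0 + phi_scale/mu) * scatter.
#' @param lib_sdlog lognormal sd of library-size factors.
#' @param patient_sdlog per-gene, per-patient baseline effect (log2 sd)
#'   shared between the tumor and normal sample of a pair.
#' @param mirna_block list: `n_mirna` total miRNAs, `n_active` planted
#'   repressors (up in tumor), `targets_per` targets per active miRNA,
#'   `slope` repression slope (log2 mRNA per log2 miRNA), `noise_sd`
#'   residual sd of the repression, `mirna_effect` planted miRNA log2FC,
#'   `inert_per_mirna` predicted-but-inert targets per miRNA (context
#'   score below the cutoff, no planted repression), `decoys_per_mirna`
#'   decoy rows with context score above the cutoff, `meanlog`/`sdlog`
#'   miRNA baseline means.
#' @param geneset_block list: `n_sets` total sets, `set_size` range,
#'   `n_up`/`n_down` planted-signal sets per direction, `signal_frac`
#'   fraction of a planted set drawn from planted genes.
#' @param ortho_one_to_many fraction of genes given a second ortholog.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       timepoints = c(1, 4, 7, 14, 21, 30, 45, 60, 120, 160),
                       n_injured_per_tp = 4L,
                       n_sham_per_tp = 3L,
                       n_healthy = 4L,
                       n_pairs = 15L,
                       archetype_curves = default_archetypes(timepoints),
                       frac_de = 0.25,
                       frac_de_tumor = 0.1,
                       tumor_overlap = 0.5,
                       effect_size = 2,
                       sham_scale = 0.4,
                       sham_end = 30,
                       baseline_meanlog = log(150),
                       baseline_sdlog = 1.2,
                       dispersion = list(phi0 = 0.04, phi_scale = 3, sdlog = 0.25),
                       lib_sdlog = 0.3,
                       patient_sdlog = 0.5,
                       mirna_block = list(n_mirna = 60L, n_active = 3L,
                                          targets_per = 20L, slope = -1,
                                          noise_sd = 0.2, mirna_effect = 2,
                                          inert_per_mirna = 20L,
                                          decoys_per_mirna = 10L,
                                          meanlog = log(400), sdlog = 1),
                       geneset_block = list(n_sets = 40L, set_size = c(25L, 60L),
                                            n_up = 3L, n_down = 3L,
                                            signal_frac = 0.8),
                       ortho_one_to_many = 0.1) {
  cfg <- as.list(environment())
  cfg$archetype_curves <- as.matrix(archetype_curves)
  with(cfg, {
    for (f in c(frac_de, frac_de_tumor, tumor_overlap, geneset_block$signal_frac))
      if (f < 0 || f > 1) stopf("fractions must lie in [0, 1]")
    if (any(diff(timepoints) <= 0)) stopf("timepoints must be strictly increasing")
    if (any(timepoints < 0)) stopf("timepoints must be non-negative")
    for (k in c(n_genes, n_injured_per_tp, n_sham_per_tp, n_healthy, n_pairs))
      if (k < 1) stopf("replicate and size counts must be positive")
    if (frac_de > 0 && nrow(cfg$archetype_curves) == 0)
      stopf("archetype_curves is empty while frac_de > 0")
    if (ncol(cfg$archetype_curves) != length(timepoints))
      stopf("archetype_curves must have one column per timepoint")
    if (sham_scale < 0 || sham_scale >= 1) stopf("sham_scale must be in [0, 1)")
    if (max(geneset_block$set_size) > n_genes)
      stopf("requested set size exceeds the gene universe")
  })
  class(cfg) <- "sim_config"
  cfg
}

# Gene-level ground truth shared between the time course and the cohort.
# Deterministic in config: both simulators and the emit_* fixtures call
# this and see the same universe.
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, 1L, {
    n <- config$n_genes
    genes <- sprintf("gene%05d", seq_len(n))
    mu0 <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
    dsp <- config$dispersion
    phi <- (dsp$phi0 + dsp$phi_scale / mu0) * rlnorm(n, 0, dsp$sdlog)

    arch <- rep(NA_integer_, n)
    n_tc <- round(config$frac_de * n)
    k <- nrow(config$archetype_curves)
    if (n_tc > 0)
      arch[sample.int(n, n_tc)] <- rep_len(seq_len(k), n_tc)[sample.int(n_tc)]

    # archetype direction = sign at the curve's largest excursion
    arch_dir <- apply(config$archetype_curves, 1,
                      function(cv) sign(cv[which.max(abs(cv))]))

    tumor_lfc <- rep(0, n)
    n_tum <- round(config$frac_de_tumor * n)
    overlap_pool <- which(!is.na(arch))
    overlap_pool <- overlap_pool[runif(length(overlap_pool)) < config$tumor_overlap]
    if (length(overlap_pool) > n_tum)
      overlap_pool <- overlap_pool[seq_len(n_tum)]
    tumor_lfc[overlap_pool] <- config$effect_size * arch_dir[arch[overlap_pool]]
    rest <- setdiff(which(is.na(arch)), overlap_pool)
    extra <- n_tum - length(overlap_pool)
    if (extra > 0) {
      idx <- sample(rest, min(extra, length(rest)))
      tumor_lfc[idx] <- config$effect_size *
        sample(c(-1, 1), length(idx), replace = TRUE)
    }

    mb <- config$mirna_block
    mirnas <- sprintf("mir-%03d", seq_len(mb$n_mirna))
    mirna_mu <- rlnorm(mb$n_mirna, mb$meanlog, mb$sdlog)
    active <- if (mb$n_active > 0) sort(sample.int(mb$n_mirna, mb$n_active)) else integer()
    free <- which(is.na(arch) & tumor_lfc == 0)
    targets <- list()
    for (m in active) {
      if (length(free) < mb$targets_per)
        stopf("not enough unplanted genes for miRNA targets")
      pick <- sample(free, mb$targets_per)
      free <- setdiff(free, pick)
      targets[[mirnas[m]]] <- genes[pick]
    }

    gs <- config$geneset_block
    sizes <- round(runif(gs$n_sets, gs$set_size[1], gs$set_size[2]))
    set_names <- sprintf("SET_%03d", seq_len(gs$n_sets))
    set_dir <- rep("none", gs$n_sets)
    set_dir[seq_len(gs$n_up)] <- "up"
    set_dir[gs$n_up + seq_len(gs$n_down)] <- "down"
    up_pool <- which(tumor_lfc > 0); down_pool <- which(tumor_lfc < 0)
    sets <- vector("list", gs$n_sets); names(sets) <- set_names
    for (i in seq_len(gs$n_sets)) {
      pool <- switch(set_dir[i], up = up_pool, down = down_pool, integer())
      n_sig <- if (set_dir[i] == "none") 0 else
        min(round(gs$signal_frac * sizes[i]), length(pool))
      sig <- if (n_sig > 0) sample(pool, n_sig) else integer()
      bg <- sample(setdiff(seq_len(n), sig), sizes[i] - n_sig)
      sets[[i]] <- genes[sort(c(sig, bg))]
    }
    # one planted set per active miRNA: its targets plus background, so
    # the anticorrelation screen's target enrichment has a true positive
    for (mi in names(targets)) {
      tg <- match(targets[[mi]], genes)
      bg <- sample(setdiff(seq_len(n), tg), length(tg))
      nm <- sprintf("SET_%s", toupper(gsub("-", "_", mi)))
      sets[[nm]] <- genes[sort(c(tg, bg))]
      set_dir[nm] <- "mirna"
    }
    set_names <- names(sets)

    one2many <- runif(n) < config$ortho_one_to_many
    list(genes = genes, mu0 = mu0, phi = phi,
         archetype = stats::setNames(arch, genes),
         archetype_names = rownames(config$archetype_curves),
         tumor_lfc = stats::setNames(tumor_lfc, genes),
         mirnas = mirnas, mirna_mu = mirna_mu,
         active_mirnas = mirnas[active], mirna_targets = targets,
         sets = sets, set_direction = stats::setNames(set_dir, set_names),
         one2many = stats::setNames(one2many, genes))
  })
}

nb_draw <- function(mu, phi) {
  n <- length(mu)
  matrix(rnbinom(n, mu = mu, size = 1 / phi), nrow = nrow(mu),
         dimnames = dimnames(mu))
}

#' Simulate the injury time course
#'
#' Draws negative-binomial counts (variance mu + phi mu^2) for injured
#' and sham fish at every timepoint plus healthy controls. Injured
#' samples of planted genes follow `mu * 2^(effect_size * curve(t))`;
#' sham samples carry a transient surgery effect (`sham_scale` of the
#' same curve, linearly forced to zero by `sham_end` days); healthy
#' samples sit at baseline. Library sizes are lognormal so normalization
#' has real work to do.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [count_matrix()]) and `truth` (planted
#'   archetypes, per-sample library factors, and the shared gene-level
#'   truth).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim_truth(config)
  tps <- config$timepoints
  with_stream(config$seed, 2L, {
    ids <- c(
      unlist(lapply(tps, function(t)
        sprintf("inj_t%g_r%d", t, seq_len(config$n_injured_per_tp)))),
      unlist(lapply(tps, function(t)
        sprintf("sham_t%g_r%d", t, seq_len(config$n_sham_per_tp)))),
      sprintf("healthy_r%d", seq_len(config$n_healthy)))
    cond <- c(rep("injured", length(tps) * config$n_injured_per_tp),
              rep("sham", length(tps) * config$n_sham_per_tp),
              rep("healthy", config$n_healthy))
    tp <- c(rep(tps, each = config$n_injured_per_tp),
            rep(tps, each = config$n_sham_per_tp),
            rep(NA_real_, config$n_healthy))
    libfac <- rlnorm(length(ids), 0, config$lib_sdlog)

    n <- config$n_genes
    zgenes <- paste0("z", truth$genes)  # zebrafish-style IDs, 1:1 backbone
    lfc <- matrix(0, n, length(ids), dimnames = list(zgenes, ids))
    planted <- which(!is.na(truth$archetype))
    curves <- config$effect_size * config$archetype_curves
    for (j in seq_along(ids)) {
      if (cond[j] == "healthy") next
      ti <- match(tp[j], tps)
      amp <- if (cond[j] == "injured") 1 else
        config$sham_scale * max(0, 1 - tp[j] / config$sham_end)
      lfc[planted, j] <- amp * curves[truth$archetype[planted], ti]
    }
    mu <- truth$mu0 * outer(rep(1, n), libfac) * 2^lfc
    dimnames(mu) <- dimnames(lfc)
    counts <- nb_draw(mu, truth$phi)
    meta <- data.frame(sample_id = ids, condition = cond, timepoint = tp,
                       pair_id = NA_character_)
    truth$timecourse_lib_factors <- stats::setNames(libfac, ids)
    truth$zebrafish_archetype <- stats::setNames(truth$archetype, zgenes)
    list(counts = count_matrix(counts, meta), truth = truth)
  })
}

#' Simulate a paired tumor--normal cohort with a miRNA block
#'
#' Each patient contributes one tumor and one normal sample sharing a
#' per-gene patient baseline effect (log2 sd `patient_sdlog`); planted
#' tumor genes are shifted by their planted log2FC. Active miRNAs are up
#' in tumor samples (sample-specific log2 shift around `mirna_effect`)
#' and push their target genes down proportionally to the repression
#' slope, plus noise -- this is what the anticorrelation screen is meant
#' to recover.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (mRNA [count_matrix()]), `mirna_counts`
#'   (miRNA [count_matrix()] on the same samples) and `truth`.
#' @export
simulate_paired_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_pairs < 3) stopf("n_pairs must be >= 3")
  truth <- sim_truth(config)
  mb <- config$mirna_block
  bad <- setdiff(unlist(truth$mirna_targets), truth$genes)
  if (length(bad)) stopf("miRNA targets reference absent genes")
  with_stream(config$seed, 3L, {
    np <- config$n_pairs
    pair_id <- sprintf("P%02d", seq_len(np))
    ids <- c(sprintf("%s_tumor", pair_id), sprintf("%s_normal", pair_id))
    cond <- rep(c("tumor", "normal"), each = np)
    libfac <- rlnorm(length(ids), 0, config$lib_sdlog)
    n <- config$n_genes

    # patient effects shared by the two samples of a pair
    pe <- matrix(rnorm(n * np, 0, config$patient_sdlog), n, np)
    lfc <- cbind(pe, pe)
    dimnames(lfc) <- list(truth$genes, ids)
    lfc[, seq_len(np)] <- lfc[, seq_len(np)] + truth$tumor_lfc

    # miRNA abundances: active ones shifted up in tumor, sample by sample
    nm <- mb$n_mirna
    mpe <- matrix(rnorm(nm * np, 0, 0.3), nm, np)
    mshift <- matrix(0, nm, 2 * np, dimnames = list(truth$mirnas, ids))
    mshift[, seq_len(np)] <- mpe
    mshift[, np + seq_len(np)] <- mpe
    act <- match(names(truth$mirna_targets), truth$mirnas)
    if (length(act))
      mshift[act, seq_len(np)] <- mshift[act, seq_len(np)] +
        matrix(rnorm(length(act) * np, mb$mirna_effect, 0.3),
               length(act), np)

    # repression: target log2 expression follows slope * miRNA shift
    for (mi in names(truth$mirna_targets)) {
      tg <- match(truth$mirna_targets[[mi]], truth$genes)
      dev <- mshift[mi, ]
      lfc[tg, ] <- lfc[tg, ] +
        outer(rep(mb$slope, length(tg)), dev) +
        matrix(rnorm(length(tg) * length(dev), 0, mb$noise_sd),
               length(tg), length(dev))
    }

    mu <- truth$mu0 * outer(rep(1, n), libfac) * 2^lfc
    dimnames(mu) <- dimnames(lfc)
    counts <- nb_draw(mu, truth$phi)
    mirna_phi <- config$dispersion$phi0 +
      config$dispersion$phi_scale / truth$mirna_mu
    mmu <- truth$mirna_mu * outer(rep(1, nm), libfac) * 2^mshift
    dimnames(mmu) <- dimnames(mshift)
    mirna_counts <- nb_draw(mmu, pmax(mirna_phi, 1e-8))

    meta <- data.frame(sample_id = ids, condition = cond,
                       timepoint = NA_real_,
                       pair_id = rep(pair_id, 2))
    truth$cohort_lib_factors <- stats::setNames(libfac, ids)
    list(counts = count_matrix(counts, meta),
         mirna_counts = count_matrix(mirna_counts, meta),
         truth = truth)
  })
}

#' Fixture emitters: gene sets, ortholog map, predicted targets
#'
#' Deterministic companions to the simulators (same config, same
#' universe). `emit_genesets` returns the planted gene-set collection
#' (human-style IDs). `emit_orthomap` returns a two-column ortholog
#' table mapping every human-style gene to a zebrafish-style partner
#' (`z<gene>`), with a configurable fraction of 1:many rows
#' (`z<gene>.2`). `emit_targets` returns a TargetScan-like table:
#' planted miRNA--target rows carry context scores < -0.2,
#' predicted-but-inert rows also score < -0.2 (they must be rejected by
#' the correlation screen), decoy rows score >= -0.2 (they must be
#' removed by the score filter).
#'
#' @param config a [sim_config()].
#' @return `emit_genesets`: named list of gene vectors with a
#'   `direction` attribute; `emit_orthomap`: data.frame `human_gene`,
#'   `zebrafish_gene`; `emit_targets`: data.frame `mirna_id`, `gene_id`,
#'   `context_score`.
#' @export
emit_genesets <- function(config) {
  truth <- sim_truth(config)
  structure(truth$sets, direction = truth$set_direction)
}

#' @rdname emit_genesets
#' @export
emit_orthomap <- function(config) {
  truth <- sim_truth(config)
  out <- data.frame(human_gene = truth$genes,
                    zebrafish_gene = paste0("z", truth$genes))
  if (any(truth$one2many)) {
    dup <- truth$genes[truth$one2many]
    out <- rbind(out, data.frame(human_gene = dup,
                                 zebrafish_gene = paste0("z", dup, ".2")))
  }
  out[order(out$human_gene, out$zebrafish_gene), , drop = FALSE]
}

#' @rdname emit_genesets
#' @export
emit_targets <- function(config) {
  truth <- sim_truth(config)
  mb <- config$mirna_block
  with_stream(config$seed, 4L, {
    rows <- list()
    for (mi in names(truth$mirna_targets)) {
      tg <- truth$mirna_targets[[mi]]
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = mi, gene_id = tg,
        context_score = runif(length(tg), -0.7, -0.25))
    }
    for (mi in truth$mirnas) {
      if (mb$inert_per_mirna > 0) {
        g <- sample(setdiff(truth$genes, truth$mirna_targets[[mi]]),
                    mb$inert_per_mirna)
        rows[[length(rows) + 1]] <- data.frame(
          mirna_id = mi, gene_id = g,
          context_score = runif(length(g), -0.7, -0.21))
      }
      if (mb$decoys_per_mirna > 0) {
        g <- sample(setdiff(truth$genes, truth$mirna_targets[[mi]]),
                    mb$decoys_per_mirna)
        rows[[length(rows) + 1]] <- data.frame(
          mirna_id = mi, gene_id = g,
          context_score = runif(length(g), -0.19, -0.01))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write the simulated inputs to a directory
#'
#' Emits the full on-disk dialect consumed by the pipeline: count and
#' metadata TSVs for both designs, the GMT collection, the ortholog TSV,
#' the predicted-target TSV and the ground truth as JSON.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tc <- simulate_timecourse(config)
  co <- simulate_paired_cohort(config)
  p <- function(f) file.path(outdir, f)
  write_counts(tc$counts, p("timecourse_counts.tsv"), p("timecourse_samples.tsv"))
  write_counts(co$counts, p("cohort_counts.tsv"), p("cohort_samples.tsv"))
  write_counts(co$mirna_counts, p("cohort_mirna_counts.tsv"),
               p("cohort_mirna_samples.tsv"))
  sets <- emit_genesets(config)
  write_gmt(sets, p("genesets.gmt"),
            descriptions = paste0("planted:", attr(sets, "direction")))
  write.table(emit_orthomap(config), p("orthologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(emit_targets(config), p("targets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- co$truth
  truth_json <- list(
    archetype = as.list(truth$archetype[!is.na(truth$archetype)]),
    archetype_names = truth$archetype_names,
    tumor_lfc = as.list(truth$tumor_lfc[truth$tumor_lfc != 0]),
    set_direction = as.list(truth$set_direction),
    active_mirnas = truth$active_mirnas,
    mirna_targets = truth$mirna_targets,
    timecourse_lib_factors = as.list(tc$truth$timecourse_lib_factors),
    cohort_lib_factors = as.list(truth$cohort_lib_factors))
  jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list.files(outdir, full.names = TRUE))
}
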