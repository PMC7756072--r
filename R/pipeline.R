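#' Pipeline run configuration
#'
#' A single validated document holding every stage threshold (the
#' workflow's standard cutoffs as defaults) plus the simulation
#' configuration. Unknown keys are rejected.
#'
#' @param ... overrides for the defaults; `sim` may be a [sim_config()]
#'   or a list of [sim_config()] arguments.
#' @param yaml_path optional YAML file whose top-level keys are the
#'   same overrides.
#' @return an object of class `run_config`.
#' @export
run_config <- function(..., yaml_path = NULL) {
  defaults <- list(
    seed = 1L,
    sim = list(),
    deg_fdr = 0.01, deg_lfc = 1, relax_fdr = 0.05, relax_min = 50,
    tau = 7,
    clusters = 5L, fuzzifier = 1.25, membership = 0.7,
    cluster_ora_fdr = 0.1, gage_fdr = 0.01,
    share_cut = 0.98, edge_cut = 0.4,
    context_cut = -0.2, rho_cut = -0.4, interaction_fdr = 0.05,
    overlap_fdr = 0.01, top_k = 15L, target_p = 0.01,
    min_cpm = 1, min_samples = 3, prior_count = 0.5, prior_df = 4)
  over <- list(...)
  if (!is.null(yaml_path))
    over <- utils::modifyList(yaml::read_yaml(yaml_path), over)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (!inherits(cfg$sim, "sim_config")) {
    cfg$sim$seed <- cfg$sim$seed %||% cfg$seed
    cfg$sim <- do.call(sim_config, cfg$sim)
  }
  with(cfg, {
    for (x in c(deg_fdr, relax_fdr, cluster_ora_fdr, gage_fdr,
                interaction_fdr, overlap_fdr, target_p, membership))
      if (x < 0 || x > 1) stopf("probability thresholds must lie in [0, 1]")
    if (share_cut <= 0 || share_cut > 1 || edge_cut < 0 || edge_cut > 1)
      stopf("sharing cutoffs must lie in (0, 1]")
    if (rho_cut >= 0 || context_cut >= 0)
      stopf("rho_cut and context_cut are negative thresholds")
    if (clusters < 2 || fuzzifier <= 1) stopf("invalid clustering parameters")
    if (tau <= 0) stopf("tau must be positive")
  })
  class(cfg) <- "run_config"
  cfg
}

with_stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate, normalize, time-course DE, trajectory clustering,
#' enrichment, term network, cohort DE + paired gene-set statistic,
#' cross-condition comparison and the miRNA screen end to end on the
#' synthetic study, writing every stage output plus a reproducibility
#' manifest (`manifest.json`) recording the package version, the
#' canonical configuration hash and the MD5 checksum of every emitted
#' file. Reruns with the same configuration produce byte-identical
#' manifests. A failing stage aborts with the stage name; outputs of
#' earlier stages are retained.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @param skip stage names to skip (among `simulate`, `cluster`,
#'   `network`, `compare`, `mirna`).
#' @return the manifest, invisibly.
#' @export
run_all <- function(config, outdir, skip = character()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  ran <- character(0)

  tc <- with_stage("simulate", simulate_timecourse(config$sim))
  co <- with_stage("simulate", simulate_paired_cohort(config$sim))
  sets <- emit_genesets(config$sim)
  orthomap <- emit_orthomap(config$sim)
  targets <- emit_targets(config$sim)
  if (!"simulate" %in% skip) {
    with_stage("simulate", write_simulation(config$sim, outdir))
    ran <- c(ran, "simulate")
  }

  norm <- with_stage("normalize", {
    tc_f <- filter_low_expression(tc$counts, config$min_cpm, config$min_samples)
    co_f <- filter_low_expression(co$counts, config$min_cpm, config$min_samples)
    list(tc_f = tc_f, co_f = co_f,
         tc_fac = tmm_factors(tc_f), co_fac = tmm_factors(co_f))
  })
  write.table(norm$tc_fac, p("timecourse_norm_factors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(norm$co_fac, p("cohort_norm_factors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ran <- c(ran, "normalize")

  traj <- with_stage("timecourse", {
    model <- control_weights(config$sim$timepoints, config$tau)
    timecourse_de(norm$tc_f, norm$tc_fac, model,
                  prior_df = config$prior_df,
                  prior_count = config$prior_count)
  })
  degs <- union_degs(traj, config$deg_fdr, config$deg_lfc)
  for (nm in c("log2FC", "fdr"))
    write.table(data.frame(gene_id = rownames(traj[[nm]]), traj[[nm]],
                           check.names = FALSE),
                p(sprintf("trajectory_%s.tsv", tolower(nm))), sep = "\t",
                quote = FALSE, row.names = FALSE)
  ran <- c(ran, "timecourse")

  cores <- NULL; assign_obj <- NULL
  if (!"cluster" %in% skip) {
    with_stage("cluster", {
      z <- zscore_rows(traj$log2FC[degs, , drop = FALSE])
      assign_obj <- fuzzy_cmeans(z, c = config$clusters,
                                 m = config$fuzzifier, seed = config$seed)
      cores <- core_genes(assign_obj, config$membership)
    })
    write.table(data.frame(gene_id = rownames(assign_obj$membership),
                           assign_obj$membership, check.names = FALSE),
                p("cluster_membership.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(cluster = rownames(assign_obj$centers),
                           assign_obj$centers, check.names = FALSE),
                p("cluster_centers.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    keep <- lengths(cores$sets) > 0
    if (any(keep)) write_gmt(cores$sets[keep], p("cluster_cores.gmt"))
    ran <- c(ran, "cluster")
  }

  sets_z <- lapply(sets, map_term_genes, map = orthomap, mode = "expand",
                   from = "human")
  cluster_ora <- NULL
  if (!is.null(cores)) {
    cluster_ora <- with_stage("enrich", {
      cl_dir <- apply(assign_obj$centers, 1,
                      function(v) if (v[which.max(abs(v))] >= 0) "up" else "down")
      res <- list()
      for (cl in names(cores$sets)) {
        if (!length(cores$sets[[cl]])) next
        r <- ora_fisher(cores$sets[[cl]], sets_z, rownames(norm$tc_f$counts))
        r$condition <- cl
        r$direction <- cl_dir[[cl]]
        res[[cl]] <- r
      }
      do.call(rbind, res)
    })
    write.table(cluster_ora, p("cluster_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ran <- c(ran, "enrich")
  }

  if (!"network" %in% skip && !is.null(cluster_ora)) {
    with_stage("network", {
      sig <- cluster_ora[cluster_ora$fdr < config$cluster_ora_fdr, ]
      if (nrow(sig)) {
        per_cl <- lapply(split(sig, sig$condition), function(d)
          data.frame(term = d$term, p = d$p,
                     genes = I(lapply(sets_z[d$term], intersect,
                                      rownames(norm$tc_f$counts)))))
        net <- build_network(per_cl, config$edge_cut, config$share_cut)
        export_term_network(net, p("term_network.graphml"),
                            p("term_network.gexf"))
      }
    })
    ran <- c(ran, "network")
  }

  de <- with_stage("de", call_degs(
    paired_de(norm$co_f, norm$co_fac, prior_df = config$prior_df,
              prior_count = config$prior_count),
    fdr_cut = config$deg_fdr, lfc_cut = config$deg_lfc,
    relax_fdr = config$relax_fdr, relax_min = config$relax_min))
  write_de_result(de, p("cohort_de.tsv"))
  gage <- with_stage("gage", {
    expr_co <- log_cpm(norm$co_f, norm$co_fac, config$prior_count)
    md <- norm$co_f$metadata
    pid <- intersect(md$pair_id[md$condition == "tumor"],
                     md$pair_id[md$condition == "normal"])
    pr <- data.frame(
      tumor = md$sample_id[match(pid, ifelse(md$condition == "tumor",
                                             md$pair_id, NA))],
      normal = md$sample_id[match(pid, ifelse(md$condition == "normal",
                                              md$pair_id, NA))])
    g <- gage_paired(expr_co, pr, sets)
    g$condition <- "cohort"
    g
  })
  write.table(gage, p("cohort_gage.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ran <- c(ran, "de", "gage")

  if (!"compare" %in% skip && !is.null(cluster_ora)) {
    with_stage("compare", {
      stacked <- rbind(
        cluster_ora[, c("term", "condition", "direction", "p", "fdr")],
        gage[, c("term", "condition", "direction", "p", "fdr")])
      cuts <- c(stats::setNames(
        rep(list(list(stat = "fdr", cut = config$cluster_ora_fdr)),
            length(unique(cluster_ora$condition))),
        unique(cluster_ora$condition)),
        list(cohort = list(stat = "fdr", cut = config$gage_fdr)))
      sig <- significance_matrix(stacked, cuts)
      write.table(data.frame(term = rownames(sig), unclass(sig),
                             check.names = FALSE),
                  p("significance_matrix.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(concordance(sig, unique(cluster_ora$condition), "cohort"),
                  p("concordance.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      hc <- hclust_binary(sig)
      jsonlite::write_json(list(row_order = rownames(sig)[hc$row_order],
                                col_order = colnames(sig)[hc$col_order]),
                           p("dendrogram_orders.json"), auto_unbox = TRUE)
    })
    ran <- c(ran, "compare")
  }

  if (!"mirna" %in% skip) {
    with_stage("mirna", {
      mi_f <- filter_low_expression(
        co$mirna_counts, config$min_cpm,
        min(config$min_samples, ncol(co$mirna_counts$counts)))
      mi_fac <- tmm_factors(mi_f)
      mi_de <- call_degs(paired_de(mi_f, mi_fac, prior_df = config$prior_df),
                         fdr_cut = config$deg_fdr, lfc_cut = config$deg_lfc,
                         relax_fdr = config$relax_fdr,
                         relax_min = config$relax_min)
      expr_co <- log_cpm(norm$co_f, norm$co_fac, config$prior_count)
      expr_mi <- log_cpm(mi_f, mi_fac, config$prior_count)
      inter <- correlate_pairs(
        expr_co, expr_mi, filter_targets(targets, config$context_cut),
        mrna_calls = stats::setNames(de$call, de$gene_id),
        mirna_calls = stats::setNames(mi_de$call, mi_de$gene_id),
        rho_cut = config$rho_cut, fdr_cut = config$interaction_fdr)
      write.table(inter, p("interactions.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      groups <- top_k_groups(
        merge_mirnas(inter, rownames(expr_co), config$overlap_fdr),
        config$top_k)
      jsonlite::write_json(groups, p("mirna_groups.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      enr <- enrich_targets(groups, sets, rownames(expr_co), config$target_p)
      if (!is.null(enr))
        write.table(enr, p("mirna_target_enrichment.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    })
    ran <- c(ran, "mirna")
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  sums <- tools::md5sum(file.path(outdir, files))
  names(sums) <- files
  manifest <- list(
    package = "regenecomp",
    version = as.character(utils::packageVersion("regenecomp")),
    seed = config$seed,
    config_md5 = digest_md5(cfg_json),
    stages = ran,
    files = as.list(sums))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# md5 of an in-memory string (tools::md5sum only hashes files)
digest_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeChar(as.character(x), f, eos = NULL)
  unname(tools::md5sum(f))
}
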