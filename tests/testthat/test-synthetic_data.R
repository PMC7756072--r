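test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(seed = 1, n_genes = 100), "sim_config")
  expect_error(sim_config(frac_de = 1.2), "fractions")
  expect_error(sim_config(timepoints = c(4, 4, 7)), "strictly increasing")
  expect_error(sim_config(n_healthy = 0), "positive")
  expect_error(sim_config(archetype_curves = matrix(0, 0, 10), frac_de = 0.2),
               "empty")
  expect_error(sim_config(n_genes = 30,
                          geneset_block = list(n_sets = 2, set_size = c(40, 50),
                                               n_up = 0, n_down = 0,
                                               signal_frac = 0.5)),
               "exceeds")
})

test_that("the same seed reproduces bit-identical simulations", {
  cfg <- sim_config(seed = 42, n_genes = 300)
  a <- simulate_timecourse(cfg); b <- simulate_timecourse(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  ca <- simulate_paired_cohort(cfg); cb <- simulate_paired_cohort(cfg)
  expect_identical(ca$counts$counts, cb$counts$counts)
  expect_identical(ca$mirna_counts$counts, cb$mirna_counts$counts)
  expect_identical(emit_targets(cfg), emit_targets(cfg))
  d <- sim_config(seed = 43, n_genes = 300)
  expect_false(identical(simulate_timecourse(d)$counts$counts,
                         a$counts$counts))
})

test_that("planted-gene bookkeeping sums to the configured fraction", {
  cfg <- sim_config(seed = 3, n_genes = 2000, frac_de = 0.25)
  tc <- simulate_timecourse(cfg)
  arch <- tc$truth$archetype
  expect_equal(sum(!is.na(arch)), 500)
  expect_equal(as.vector(table(arch)), rep(100, 5))
  expect_true(all(names(arch) %in% sub("^z", "", rownames(tc$counts$counts))))
})

test_that("planted effects reach the configured magnitude at the peak", {
  # Monte-Carlo check of the generator against its own parameters:
  # many injured replicates at one timepoint, effect size 2 at the peak.
  cfg <- sim_config(seed = 9, n_genes = 400, timepoints = c(1, 4, 7),
                    n_injured_per_tp = 50, n_sham_per_tp = 2,
                    n_healthy = 50, lib_sdlog = 0,
                    archetype_curves = matrix(c(0.5, 1, 0.5), 1,
                                              dimnames = list("peak4", NULL)),
                    frac_de = 0.25, effect_size = 2)
  tc <- simulate_timecourse(cfg)
  md <- tc$counts$metadata
  inj4 <- md$sample_id[md$condition == "injured" & md$timepoint == 4]
  heal <- md$sample_id[md$condition == "healthy"]
  planted <- paste0("z", names(tc$truth$archetype)[!is.na(tc$truth$archetype)])
  ratio <- rowMeans(tc$counts$counts[planted, inj4]) /
    pmax(rowMeans(tc$counts$counts[planted, heal]), 1e-9)
  expect_gt(median(ratio), 2^2 / 2)
  expect_lt(median(ratio), 2^2 * 2)
})

test_that("a null simulation carries no systematic group differences", {
  cfg <- null_config(1, n_genes = 1000)
  tc <- simulate_timecourse(cfg)
  f <- tmm_factors(filter_low_expression(tc$counts))
  traj <- timecourse_de(filter_low_expression(tc$counts), f,
                        control_weights(cfg$timepoints))
  expect_lt(length(union_degs(traj)), 0.02 * 1000)
})

test_that("paired patient effects make the paired analysis more powerful", {
  cfg <- quiet_cohort_config(5, n_genes = 1500)
  co <- simulate_paired_cohort(cfg)
  cof <- filter_low_expression(co$counts)
  fac <- tmm_factors(cof)
  planted <- names(co$truth$tumor_lfc)[co$truth$tumor_lfc != 0]
  de_p <- call_degs(paired_de(cof, fac), fdr_cut = 0.05, lfc_cut = 1)
  # unpaired comparison on the same data: two-group moderated t
  expr <- log_cpm(cof, fac)
  md <- cof$metadata
  tum <- md$sample_id[md$condition == "tumor"]
  nor <- md$sample_id[md$condition == "normal"]
  delta <- rowMeans(expr[, tum]) - rowMeans(expr[, nor])
  s2 <- (apply(expr[, tum], 1, var) + apply(expr[, nor], 1, var)) / 2
  tt <- delta / sqrt(2 * s2 / length(tum))
  p <- 2 * pt(-abs(tt), df = 2 * length(tum) - 2)
  unpaired_up <- sum(bh_fdr(p) < 0.05 & abs(delta) > 1)
  recall_paired <- mean(planted %in% de_p$gene_id[de_p$call != "ns"])
  recall_unpaired <- unpaired_up / max(length(planted), 1)
  expect_gt(recall_paired, recall_unpaired)
  expect_gt(recall_paired, 0.8)
})

test_that("fixture emitters respect the planted structure", {
  cfg <- sim_config(seed = 2, n_genes = 500)
  sets <- emit_genesets(cfg)
  expect_true(all(lengths(sets) > 0))
  dirs <- attr(sets, "direction")
  expect_equal(sum(dirs == "up"), 3)
  expect_equal(sum(dirs == "down"), 3)
  map <- emit_orthomap(cfg)
  expect_true(all(grepl("^zgene", map$zebrafish_gene)))
  expect_gt(nrow(map), 500)  # some 1:many rows at the default fraction
  # a zero 1:many fraction gives a bijection
  bij <- emit_orthomap(sim_config(seed = 2, n_genes = 500, ortho_one_to_many = 0))
  expect_equal(nrow(bij), 500)
  expect_false(anyDuplicated(bij$human_gene) > 0)
  expect_false(anyDuplicated(bij$zebrafish_gene) > 0)
  tg <- emit_targets(cfg)
  truthful <- simulate_paired_cohort(cfg)$truth
  for (mi in names(truthful$mirna_targets)) {
    planted_rows <- tg[tg$mirna_id == mi &
                         tg$gene_id %in% truthful$mirna_targets[[mi]], ]
    expect_true(all(planted_rows$context_score < -0.2))
  }
  gmt_path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt_path, descriptions = attr(sets, "direction"))
  back <- read_gmt(gmt_path)
  expect_identical(unname(lengths(back)), unname(lengths(sets)))
  expect_identical(back[[1]], sets[[1]])
})

test_that("NB marginals match the mean-dispersion parameterization", {
  # 200 healthy replicates, fixed library size: counts are iid NB per
  # gene, so the empirical variance should track mu + phi mu^2.
  cfg <- sim_config(seed = 8, n_genes = 500, frac_de = 0,
                    n_injured_per_tp = 1, n_sham_per_tp = 1,
                    n_healthy = 200, lib_sdlog = 0)
  tc <- simulate_timecourse(cfg)
  heal <- tc$counts$metadata$sample_id[tc$counts$metadata$condition == "healthy"]
  y <- tc$counts$counts[, heal]
  mu_hat <- rowMeans(y)
  keep <- mu_hat > 20
  v_hat <- apply(y, 1, var)
  mu_true <- tc$truth$mu0
  v_true <- mu_true + tc$truth$phi * mu_true^2
  ratio <- v_hat[keep] / v_true[keep]
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.25)
})
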