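test_that("bh_fdr matches the hand-applied step-up rule", {
  # p(i) * m / i = (.04, .04, .04, .04) after monotone enforcement
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # hand case with distinct adjusted values: p = (.001, .02, .9)
  # -> (.003, .03, .9)
  expect_equal(bh_fdr(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9))
  expect_error(bh_fdr(c(0.1, NaN)), "NaN")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("dispersion estimates recover the generating parameters", {
  mk <- function(phi, n_rep, seed, mu_log = log(200)) {
    withr::with_seed(seed, {
      mu <- rlnorm(2000, mu_log, 0.8)
      y <- if (phi == 0)
        matrix(rpois(2000 * n_rep, mu), 2000)
      else
        matrix(rnbinom(2000 * n_rep, mu = mu, size = 1 / phi), 2000)
      dimnames(y) <- list(paste0("g", 1:2000), paste0("s", 1:n_rep))
      count_matrix(y, data.frame(sample_id = colnames(y),
                                 condition = "healthy"))
    })
  }
  cm <- mk(0.2, 10, 31)
  fit <- estimate_dispersion(cm, unit_factors(cm$counts), rep("a", 10))
  expect_gt(median(fit$tagwise), 0.1)
  expect_lt(median(fit$tagwise), 0.4)
  expect_true(all(fit$tagwise >= pmin(fit$raw, fit$trend) - 1e-12))
  expect_true(all(fit$tagwise <= pmax(fit$raw, fit$trend) + 1e-12))
  # Poisson data: dispersion shrinks toward zero as replication grows
  p5 <- mk(0, 5, 32); p40 <- mk(0, 40, 33)
  m5 <- median(estimate_dispersion(p5, unit_factors(p5$counts),
                                   rep("a", 5))$tagwise)
  m40 <- median(estimate_dispersion(p40, unit_factors(p40$counts),
                                    rep("a", 40))$tagwise)
  expect_lt(m40, m5)
  expect_lt(m40, 0.02)
  # constant gene across equal libraries: raw dispersion 0
  const <- matrix(50, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  ccm <- count_matrix(const, data.frame(sample_id = colnames(const),
                                        condition = "healthy"))
  cfit <- estimate_dispersion(ccm, unit_factors(const), rep("a", 6))
  expect_equal(cfit$raw, rep(0, 4))
  expect_error(estimate_dispersion(ccm, unit_factors(const), 1:6),
               "singleton")
})

test_that("paired_de is exact on degenerate input and antisymmetric", {
  cfg <- quiet_cohort_config(17, n_genes = 400, n_pairs = 5)
  co <- simulate_paired_cohort(cfg)
  cm <- co$counts
  # tumor == normal per pair: log2FC exactly 0 everywhere, no calls
  md <- cm$metadata
  tum <- md$sample_id[md$condition == "tumor"]
  nor <- md$sample_id[md$condition == "normal"]
  dup <- cm$counts; dup[, nor] <- dup[, tum]
  dup_cm <- count_matrix(dup, md)
  fac <- unit_factors(dup)
  de0 <- call_degs(paired_de(dup_cm, fac))
  expect_equal(de0$log2FC, rep(0, nrow(dup)))
  expect_true(all(de0$call == "ns"))
  # label swap negates log2FC and keeps p-values
  fac2 <- tmm_factors(cm)
  de <- paired_de(cm, fac2)
  md_sw <- md
  md_sw$condition <- ifelse(md$condition == "tumor", "normal", "tumor")
  de_sw <- paired_de(count_matrix(cm$counts, md_sw), fac2)
  expect_equal(de_sw$log2FC, -de$log2FC, tolerance = 1e-12)
  expect_equal(de_sw$raw_p, de$raw_p, tolerance = 1e-12)
  # permuting gene order permutes the outputs
  perm <- rev(seq_len(nrow(cm$counts)))
  de_perm <- paired_de(count_matrix(cm$counts[perm, ], md), fac2)
  expect_equal(de_perm$log2FC, de$log2FC[perm], tolerance = 1e-12)
  expect_equal(de_perm$fdr, de$fdr[perm], tolerance = 1e-12)
  expect_error(paired_de(subset_cm <- count_matrix(
    cm$counts[, c(tum[1:2], nor[1:2])],
    md[md$sample_id %in% c(tum[1:2], nor[1:2]), ]), unit_factors(
      cm$counts[, c(tum[1:2], nor[1:2])])), "3 complete")
})

test_that("paired_de agrees with the limma moderated pipeline on ranks", {
  skip_if_not_installed("limma")
  cfg <- quiet_cohort_config(23, n_genes = 800, n_pairs = 8)
  co <- simulate_paired_cohort(cfg)
  cof <- filter_low_expression(co$counts)
  fac <- tmm_factors(cof)
  de <- paired_de(cof, fac)
  expr <- log_cpm(cof, fac)
  pr <- cohort_pairs(cof)
  d <- expr[, pr$tumor] - expr[, pr$normal]
  fit <- limma::eBayes(limma::lmFit(d, matrix(1, ncol(d), 1)))
  expect_equal(de$log2FC, unname(fit$coefficients[, 1]), tolerance = 1e-9)
  expect_gt(cor(rank(de$raw_p), rank(fit$p.value[, 1])), 0.99)
})

test_that("call_degs applies the thresholds and the <50-gene relaxation", {
  # hand-checkable toy table
  de <- regenecomp:::de_result(
    paste0("g", 1:10),
    log2FC = c(2, 1.5, 0.5, -2, -1.2, 3, -0.8, 1.1, -1.01, 0),
    raw_p = rep(0.5, 10))
  de$fdr <- c(0.001, 0.02, 0.001, 0.005, 0.04, 0.2, 0.001, 0.06, 0.049, 0.001)
  strict <- call_degs(de, fdr_cut = 0.01, lfc_cut = 1,
                      relax_fdr = 0.05, relax_min = 0)
  expect_identical(strict$call,
                   c("up", "ns", "ns", "down", "ns", "ns", "ns", "ns", "ns", "ns"))
  expect_false(attr(strict, "relaxation_applied"))
  relaxed <- call_degs(de, fdr_cut = 0.01, lfc_cut = 1,
                       relax_fdr = 0.05, relax_min = 50)
  expect_true(attr(relaxed, "relaxation_applied"))
  expect_identical(relaxed$call,
                   c("up", "up", "ns", "down", "down", "ns", "ns", "ns", "down", "ns"))
  expect_equal(attr(relaxed, "thresholds")$fdr_cut, 0.05)
  # zero significant genes even after relaxing: empty call set, no error
  de$fdr <- rep(1, 10)
  none <- call_degs(de)
  expect_true(all(none$call == "ns"))
  expect_true(attr(none, "relaxation_applied"))
})
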