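test_that("filter_targets applies the strict score cutoff and dedupes", {
  tab <- data.frame(
    mirna_id = c("m1", "m1", "m1", "m2", "m2"),
    gene_id = c("g1", "g2", "g2", "g1", "g3"),
    context_score = c(-0.19, -0.3, -0.5, -0.21, -0.2))
  out <- filter_targets(tab, score_cut = -0.2)
  expect_equal(nrow(out), 2)                       # -0.19 and -0.2 dropped
  expect_false(any(out$context_score >= -0.2))
  dup <- out[out$mirna_id == "m1" & out$gene_id == "g2", ]
  expect_equal(dup$context_score, -0.5)            # keep most negative
  expect_error(filter_targets(tab[, 1:2]), "columns")
})

test_that("correlate_pairs flags perfect anticorrelation and boundaries", {
  x <- c(1, 2, 3, 4, 5, 6)
  samples <- paste0("s", 1:6)
  # rho exactly -0.4 by construction: y = -0.4 * xc/|xc| + sqrt(0.84) * e/|e|
  xc <- scale(c(1, 2, 3, 4, 5), scale = FALSE)[, 1]
  e <- c(1, -2, 1, 0, 0)                    # orthogonal to xc
  y_boundary <- -0.4 * xc / sqrt(sum(xc^2)) + sqrt(0.84) * e / sqrt(sum(e^2))
  mirna <- rbind(m1 = x, m2 = c(x[1:5], 6), m3 = rep(2, 6))
  colnames(mirna) <- samples
  mrna <- rbind(gPerfect = -x,
                gBoundary = c(y_boundary, 0),
                gFlat = rep(1, 6))
  colnames(mrna) <- samples
  cand <- data.frame(mirna_id = c("m1", "m2", "m1", "m3"),
                     gene_id = c("gPerfect", "gBoundary", "gFlat", "gPerfect"),
                     context_score = -0.5)
  # m2/gBoundary uses only the first five samples' structure, so test
  # it on its own five-sample matrices for the exact value
  inter <- suppressMessages(
    correlate_pairs(mrna, mirna, cand[c(1, 3, 4), ]))
  perfect <- inter[inter$mirna == "m1" & inter$gene == "gPerfect", ]
  expect_equal(perfect$rho, -1)
  expect_true(perfect$valid)
  expect_equal(attr(inter, "skipped"), 2L)  # both flat-vector pairs
  five <- paste0("s", 1:5)
  inter_b <- correlate_pairs(
    rbind(gBoundary = y_boundary)[, , drop = FALSE] |>
      `colnames<-`(five),
    rbind(m1 = x[1:5]) |> `colnames<-`(five),
    data.frame(mirna_id = "m1", gene_id = "gBoundary", context_score = -0.5))
  expect_equal(inter_b$rho, -0.4, tolerance = 1e-12)
  expect_false(inter_b$valid)               # rho < -0.4 is strict
  expect_error(correlate_pairs(mrna[, 1:4], mirna[, 1:4], cand), "5 shared")
})

test_that("the direction split is exclusive and exhaustive", {
  cfg <- sim_config(seed = 33, n_genes = 600, n_pairs = 8)
  co <- simulate_paired_cohort(cfg)
  cof <- filter_low_expression(co$counts)
  fac <- tmm_factors(cof)
  mif <- filter_low_expression(co$mirna_counts)
  mifac <- tmm_factors(mif)
  de <- call_degs(paired_de(cof, fac))
  mde <- call_degs(paired_de(mif, mifac))
  cand <- filter_targets(emit_targets(cfg))
  inter <- suppressMessages(correlate_pairs(
    log_cpm(cof, fac), log_cpm(mif, mifac), cand,
    mrna_calls = setNames(de$call, de$gene_id),
    mirna_calls = setNames(mde$call, mde$gene_id)))
  expect_true(all(inter$direction %in% c("miR-up/mRNA-down", "miR-down/mRNA-up")))
  mcall <- setNames(mde$call, mde$gene_id)[inter$mirna]
  gcall <- setNames(de$call, de$gene_id)[inter$gene]
  up_split <- inter$direction == "miR-up/mRNA-down"
  expect_true(all(mcall[up_split] == "up" & gcall[up_split] == "down"))
  expect_true(all(mcall[!up_split] == "down" & gcall[!up_split] == "up"))
  expect_true(all(inter$valid == (inter$rho < -0.4 & inter$fdr < 0.05)))
})

fake_interactions <- function(tsets) {
  do.call(rbind, lapply(names(tsets), function(m)
    data.frame(mirna = m, gene = tsets[[m]], rho = -0.9, p = 1e-8,
               fdr = 1e-7, valid = TRUE, direction = "miR-up/mRNA-down")))
}

test_that("merge_mirnas joins miRNAs with significant target overlap", {
  universe <- paste0("g", 1:1000)
  shared <- paste0("g", 1:20)
  tsets <- list(mA = shared, mB = shared,
                mC = paste0("g", 500:519))
  groups <- merge_mirnas(fake_interactions(tsets), universe)
  sizes <- sort(lengths(lapply(groups, `[[`, "members")))
  expect_equal(unname(sizes), c(1, 2))
  merged <- groups[[which(lengths(lapply(groups, `[[`, "members")) == 2)]]
  expect_setequal(merged$members, c("mA", "mB"))
  expect_setequal(merged$targets, shared)
  # transitive chain: A~B and B~C share enough, A~C need not
  tsets2 <- list(mA = paste0("g", 1:20),
                 mB = paste0("g", 11:30),
                 mC = paste0("g", 21:40))
  groups2 <- merge_mirnas(fake_interactions(tsets2), universe)
  expect_equal(length(groups2), 1)
  expect_setequal(groups2[[1]]$members, c("mA", "mB", "mC"))
  # the overlap p matches exhaustive enumeration
  k <- 10; a <- 20; b <- 20; N <- 1000
  p_pkg_edge <- phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  expect_equal(p_pkg_edge, hyper_tail_oracle(k, a, b, N), tolerance = 1e-12)
})

test_that("top_k_groups ranks by target count with documented tie-breaks", {
  g <- function(members, n_targets)
    list(members = members, targets = paste0("t", seq_len(n_targets)),
         member_targets = setNames(rep(n_targets, length(members)), members))
  groups <- list(g("mA", 40), g("mB", 10), g(c("mC", "mD"), 10), g("mE", 5))
  top2 <- top_k_groups(groups, 2)
  expect_equal(names(top2)[1], "mA")
  expect_equal(names(top2)[2], "mC")     # tie on 10 targets: more members
  all4 <- top_k_groups(groups, 99)
  expect_equal(length(all4), 4)
  expect_equal(names(all4), c("mA", "mC", "mB", "mE"))
})

test_that("enrich_targets flags a planted set at nominal p", {
  universe <- paste0("g", 1:500)
  sets <- list(planted = paste0("g", 1:25), other = paste0("g", 400:450))
  groups <- list(mX = list(members = "mX", targets = paste0("g", 1:20),
                           member_targets = c(mX = 20)))
  res <- enrich_targets(groups, sets, universe, p_cut = 0.01)
  expect_true(res$significant[res$term == "planted"])
  expect_false(res$significant[res$term == "other"])
  expect_identical(res$term[which.min(res$p)], "planted")
  empty <- list(mY = list(members = "mY", targets = character(0),
                          member_targets = c(mY = 0)))
  expect_message(res2 <- enrich_targets(empty, sets, universe), "skipped")
  expect_null(res2)
})
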