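# Independent oracles and small fixtures used across the suite.

# Exhaustive hypergeometric upper-tail probability by direct enumeration
# of the support: P(X >= k) for overlap X of a size-n draw with a size-K
# marked subset of an N-gene universe.
hyper_tail_oracle <- function(k, K, n, N) {
  upper <- min(K, n)
  if (k > upper) return(0)
  i <- max(k, 0):upper
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Direct implementation of the TMM trimmed weighted mean (Robinson-
# Oshlack): M-value trimming, A-value trimming, inverse asymptotic-
# variance weights, geometric-mean centering. Written independently of
# the package's normalization path.
tmm_oracle <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(j) {
    y <- counts[, j]; r <- counts[, ref]
    keep <- y > 0 & r > 0
    y <- y[keep]; r <- r[keep]
    M <- log2((y / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((y / lib[j]) * (r / lib[ref]))
    w <- (lib[j] - y) / (lib[j] * y) + (lib[ref] - r) / (lib[ref] * r)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    if (max(abs(M)) < 1e-6) return(1)
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f / exp(mean(log(f)))
}

# Best classification accuracy over all cluster-label permutations
# (Hungarian matching by exhaustion; fine for c <= 6).
perm_match_accuracy <- function(truth_lab, cluster_lab) {
  stopifnot(length(truth_lab) == length(cluster_lab))
  tl <- sort(unique(truth_lab)); cl <- sort(unique(cluster_lab))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  k <- max(length(tl), length(cl))
  best <- 0
  for (pm in perms(seq_len(k))) {
    mapped <- tl[pm[match(cluster_lab, cl)]]
    best <- max(best, mean(mapped == truth_lab, na.rm = TRUE))
  }
  best
}

# All-pairs sharing fractions (min-set denominator), brute force.
share_oracle <- function(sets) {
  nm <- names(sets)
  out <- list()
  if (length(nm) < 2) return(out)
  for (i in seq_along(nm)[-length(nm)]) for (j in (i + 1):length(nm)) {
    a <- sets[[i]]; b <- sets[[j]]
    out[[paste(nm[i], nm[j], sep = "|")]] <-
      length(intersect(a, b)) / min(length(a), length(b))
  }
  out
}

# Tiny cohort configuration used by several tests (no miRNA signal).
quiet_cohort_config <- function(seed, n_genes = 2000, n_pairs = 10,
                                frac_de_tumor = 0.1) {
  sim_config(seed = seed, n_genes = n_genes, n_pairs = n_pairs,
             frac_de_tumor = frac_de_tumor, tumor_overlap = 0,
             mirna_block = list(n_mirna = 20L, n_active = 0L,
                                targets_per = 10L, slope = -1,
                                noise_sd = 0.2, mirna_effect = 2,
                                inert_per_mirna = 10L,
                                decoys_per_mirna = 5L,
                                meanlog = log(400), sdlog = 1))
}

# Fully null configuration: no planted effects anywhere.
null_config <- function(seed, n_genes = 2000, n_pairs = 10) {
  sim_config(seed = seed, n_genes = n_genes, n_pairs = n_pairs,
             frac_de = 0, frac_de_tumor = 0,
             mirna_block = list(n_mirna = 20L, n_active = 0L,
                                targets_per = 10L, slope = -1,
                                noise_sd = 0.2, mirna_effect = 2,
                                inert_per_mirna = 30L,
                                decoys_per_mirna = 5L,
                                meanlog = log(400), sdlog = 1))
}

cohort_pairs <- function(cm) {
  md <- cm$metadata
  pid <- intersect(md$pair_id[md$condition == "tumor"],
                   md$pair_id[md$condition == "normal"])
  data.frame(
    tumor = md$sample_id[match(pid, ifelse(md$condition == "tumor", md$pair_id, NA))],
    normal = md$sample_id[match(pid, ifelse(md$condition == "normal", md$pair_id, NA))])
}

unit_factors <- function(counts) {
  lib <- colSums(counts)
  out <- data.frame(sample_id = colnames(counts), lib_size = lib,
                    tmm_factor = 1, effective_lib_size = lib,
                    row.names = NULL)
  class(out) <- c("norm_factors", "data.frame")
  out
}
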