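#' Row-wise z-score of a trajectory matrix
#'
#' Each gene's log2FC profile is centered and scaled to unit standard
#' deviation, so clustering sees shape only. Constant rows cannot be
#' standardized and are excluded with a warning.
#'
#' @param x numeric matrix (genes x timepoints) or the `log2FC` slot of
#'   a [timecourse_de()] result.
#' @return the standardized matrix (possibly fewer rows); idempotent.
#' @export
zscore_rows <- function(x) {
  if (inherits(x, "trajectory_matrix")) x <- x$log2FC
  s <- apply(x, 1, sd)
  drop <- s < 1e-12 | !is.finite(s)
  if (any(drop))
    warning(sprintf("%d constant row(s) excluded from z-scoring", sum(drop)))
  x <- x[!drop, , drop = FALSE]
  (x - rowMeans(x)) / apply(x, 1, sd)
}

kmeanspp_init <- function(x, c) {
  n <- nrow(x)
  centers <- matrix(NA_real_, c, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
  for (j in seq_len(c)[-1]) {
    prob <- d2 / sum(d2)
    if (!all(is.finite(prob)) || sum(d2) == 0)
      prob <- rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

fcm_run <- function(x, c, m, tol, max_iter) {
  n <- nrow(x); centers <- attr(x, "init")
  obj <- numeric(0)
  u <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    # membership update on distance ratios (overflow-safe); a point
    # coincident with a center gets full membership there
    dmin <- pmax(apply(d2, 1, min), 0)
    hit <- dmin < 1e-12
    ratio <- d2 / pmax(dmin, 1e-12)
    u <- ratio^(-1 / (m - 1))
    if (any(hit)) {
      u[hit, ] <- 0
      u[cbind(which(hit), max.col(-d2[hit, , drop = FALSE]))] <- 1
    }
    u <- u / rowSums(u)
    obj <- c(obj, sum(u^m * d2))
    um <- u^m
    new_centers <- (t(um) %*% x) / colSums(um)
    delta <- max(abs(new_centers - centers))
    centers <- new_centers
    if (delta < tol) break
  }
  list(membership = u, centers = centers, objective = obj,
       converged = delta < tol, iterations = iter)
}

#' Fuzzy c-means clustering of z-scored trajectories
#'
#' Soft clustering by alternating fuzzy c-means updates
#' (`u_gc = 1 / sum_k (d_gc/d_gk)^(2/(m-1))` with Euclidean distance;
#' centers are the `u^m`-weighted means) until the largest center change
#' falls below `tol`. Initialization is k-means++-style seeding from the
#' given seed with `restarts` independent starts, keeping the run with
#' the best (lowest) final objective. The recorded objective
#' `sum u^m d^2` is non-increasing across iterations by construction of
#' the updates.
#'
#' @param z standardized matrix from [zscore_rows()] (>= `c` rows).
#' @param c number of clusters (>= 2).
#' @param m fuzzifier (> 1). The default 1.25 keeps memberships
#'   informative on standardized profiles, where the classical m = 2
#'   drifts toward uniform membership.
#' @param seed integer seed; the run is deterministic given it.
#' @param tol convergence tolerance on the centers.
#' @param max_iter iteration cap (a warning flag is set if reached).
#' @param restarts number of random restarts.
#' @return an object of class `cluster_assignment`: `membership`
#'   (genes x clusters, rows summing to 1), `centers`
#'   (clusters x timepoints), `objective` trace, `converged`,
#'   `params`.
#' @export
fuzzy_cmeans <- function(z, c = 5, m = 1.25, seed = 1, tol = 1e-6,
                         max_iter = 1000, restarts = 10) {
  if (c < 2) stopf("c must be >= 2")
  if (m <= 1) stopf("fuzzifier m must be > 1")
  if (nrow(z) < c) stopf("need at least c rows to form c clusters")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_stream(seed, 100L + r, {
      attr(z, "init") <- kmeanspp_init(z, c)
      fcm_run(z, c, m, tol, max_iter)
    })
    if (is.null(best) || min(fit$objective) < min(best$objective))
      best <- fit
  }
  if (!best$converged)
    warning("fuzzy c-means did not converge within max_iter")
  dimnames(best$membership) <- list(rownames(z), paste0("cluster_", seq_len(c)))
  dimnames(best$centers) <- list(paste0("cluster_", seq_len(c)), colnames(z))
  structure(list(membership = best$membership, centers = best$centers,
                 objective = best$objective, converged = best$converged,
                 iterations = best$iterations,
                 params = list(c = c, m = m, seed = seed, tol = tol,
                               restarts = restarts)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d genes, %d clusters (m = %g, %s)\n",
              nrow(x$membership), ncol(x$membership), x$params$m,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Core genes per cluster
#'
#' A gene belongs to the core of cluster c when its membership there is
#' both the row maximum and above `threshold`; genes below the
#' threshold (and exact ties for the maximum) stay unassigned.
#'
#' @param assign a [fuzzy_cmeans()] result.
#' @param threshold membership cutoff (strict `>`).
#' @return list with `sets` (per-cluster gene vectors) and `assignment`
#'   (named vector, `NA` for unassigned genes).
#' @export
core_genes <- function(assign, threshold = 0.7) {
  u <- assign$membership
  top <- max.col(u, ties.method = "first")
  mx <- u[cbind(seq_len(nrow(u)), top)]
  tied <- rowSums(u == mx) > 1
  keep <- mx > threshold & !tied
  lab <- ifelse(keep, colnames(u)[top], NA_character_)
  names(lab) <- rownames(u)
  sets <- split(names(lab)[keep], lab[keep])
  sets <- sets[colnames(u)[colnames(u) %in% names(sets)]]
  list(sets = sets, assignment = lab, threshold = threshold)
}
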