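#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cor dist hclust lowess median p.adjust phyper
#'   pnorm prcomp pt qnorm quantile rlnorm rnbinom rnorm runif sd var IQR
#' @importFrom utils read.delim write.table head
NULL

# Run code with a derived RNG stream without disturbing the caller's RNG.
# Offsets keep every derived seed a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * offset) %% .Machine$integer.max)
}

with_stream <- function(seed, offset, code) {
  withr::with_seed(derive_seed(seed, offset), code)
}

# Empirical-Bayes variance squeeze with a fixed prior degrees of freedom.
# The prior variance is the median of the gene-wise variances (robust to
# the planted-effect tail). Returns posterior variances.
squeeze_var <- function(s2, df_resid, prior_df = 4) {
  s2 <- pmax(s2, 0)
  s0 <- stats::median(s2, na.rm = TRUE)
  (prior_df * s0 + df_resid * s2) / (prior_df + df_resid)
}

# Two-sided p-value for a moderated t statistic; handles the degenerate
# zero-variance case (exactly constant differences).
moderated_p <- function(delta, se, df) {
  p <- rep(1, length(delta))
  pos <- se > 0
  p[pos] <- 2 * stats::pt(-abs(delta[pos] / se[pos]), df = df)
  # zero variance, nonzero effect: evidence is unbounded
  p[!pos & abs(delta) > 0] <- 0
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
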