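# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Study vocabulary: regions and traits
#'
#' The three study regions and the nine leaf defense traits, in canonical
#' order: cyanogenic glycosides (`cyan`, eq. mg KCN/g), total alkaloids
#' (`alkaloids`, eq. mg atropine/g), total fiber (`fiber`, % dry mass),
#' cell wall mass (`cell_wall`, mg/cm2), total protein (`protein`, mg/cm2),
#' C:N ratio (`cn`), mass-based carbon and nitrogen (`c_mass`, `n_mass`, %),
#' and specific leaf area (`sla`, cm2/g).
#'
#' @return Character vector of region or trait names.
#' @export
jtl_regions <- function() c("France", "Japan", "USA")

#' @rdname jtl_regions
#' @export
jtl_traits <- function() {
  c("cyan", "alkaloids", "fiber", "cell_wall", "protein",
    "cn", "c_mass", "n_mass", "sla")
}

#' @keywords internal
jtl_env_vars <- function() c("soil_ph", "gli", "mat", "map")

# Traits log-transformed before analysis; cell wall mass stays on the raw
# scale (logging it increases rather than decreases skew).
logged_traits <- function() setdiff(jtl_traits(), "cell_wall")

# Traits measured as percentages, bounded in [0, 100].
percent_traits <- function() c("fiber", "c_mass", "n_mass")

# Traits where an exact zero is a valid value (assay detection floor).
zero_ok_traits <- function() c("cyan", "alkaloids")

growth_forms <- function() c("woody", "herbaceous")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible per-stage seed from a single pipeline seed
#'
#' A fixed integer derivation so that every pipeline stage has its own seed,
#' each stage can be re-run in isolation, and a single top-level seed makes
#' the whole run deterministic. The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return A single integer seed.
#' @export
#' @examples
#' stage_seed(1, "simulate")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483646 + 1)
}

# Draw sigma from its full conditional under a uniform(0, bound) prior on the
# SD scale, with k mean-zero normal "observations" and sum of squares ss.
# For k >= 2 the precision tau = sigma^-2 has a Gamma((k-1)/2, ss/2)
# conditional truncated to tau > bound^-2, drawn exactly by inverse CDF.
# For k == 1 the gamma shape is zero and the conditional is only proper
# because of the prior bound; a bounded slice sampler on sigma handles it.
draw_sigma <- function(k, ss, bound, current) {
  if (k >= 2 && ss > 0) {
    shape <- (k - 1) / 2
    rate <- ss / 2
    lo <- bound^-2
    plo <- stats::pgamma(lo, shape, rate = rate)
    plo <- min(plo, 1 - 1e-12)
    u <- stats::runif(1, plo, 1)
    tau <- stats::qgamma(u, shape, rate = rate)
    return(1 / sqrt(max(tau, lo)))
  }
  logf <- function(sigma) -k * log(sigma) - ss / (2 * sigma^2)
  slice_sample_bounded(current, logf, lower = 1e-8, upper = bound)
}

# One update of a shrinkage slice sampler on a bounded interval
# (Neal 2003, Fig. 5 variant: initial interval = full support).
slice_sample_bounded <- function(x0, logf, lower, upper) {
  logy <- logf(x0) - stats::rexp(1)
  l <- lower
  u <- upper
  for (i in 1:1000) {
    x1 <- stats::runif(1, l, u)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) l <- x1 else u <- x1
  }
  x0
}

# Monte-Carlo standard error of a chain mean via non-overlapping batch means.
mcse_mean <- function(x, n_batch = 30L) {
  n <- length(x)
  b <- max(2L, floor(n / n_batch))
  nb <- floor(n / b)
  bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * b + 1):(i * b)]), 0.0)
  stats::sd(bm) / sqrt(nb)
}
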