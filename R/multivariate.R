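# Trait-syndrome analysis: PCA of the nine traits on Z-scaled,
# posterior-mean-imputed data, plus a mixed model on the PC scores.

#' Build a complete Z-scaled trait matrix via posterior-mean imputation
#'
#' Log-transforms and Z-standardizes the traits within one growth form,
#' then replaces every missing cell with the posterior mean of its value
#' from the corresponding hierarchical model fit (see [impute_missing()]).
#' Observed cells are never altered by imputation. By default all columns
#' are re-standardized after filling, so the PCA sees exactly unit-variance
#' columns.
#'
#' @param table A [trait_table()].
#' @param posteriors Named list (by trait) of `hb_posterior` fits for the
#'   same growth form. Only traits with missing cells need a fit.
#' @param growth_form `"woody"` or `"herbaceous"`.
#' @param traits Traits to include as columns (default all nine).
#' @param restandardize Re-center/rescale columns after imputation
#'   (default `TRUE`).
#' @return A numeric matrix (populations x traits) with population IDs as
#'   rownames and the observation metadata as attribute `"meta"`.
#' @export
impute_and_scale <- function(table, posteriors = list(),
                             growth_form = c("woody", "herbaceous"),
                             traits = jtl_traits(),
                             restandardize = TRUE) {
  stopifnot(inherits(table, "trait_table"), all(traits %in% jtl_traits()))
  growth_form <- match.arg(growth_form)
  tm <- z_standardize(log_transform(table), subset = growth_form)
  data <- tm$data
  x <- as.matrix(data[, traits, drop = FALSE])
  rownames(x) <- data$population_id
  for (tr in traits) {
    miss <- which(is.na(x[, tr]))
    if (!length(miss)) next
    fit <- posteriors[[tr]]
    if (is.null(fit)) {
      stopf("trait %s has missing cells but no posterior was supplied", tr)
    }
    imp <- impute_missing(fit)
    idx <- match(rownames(x)[miss], imp$population_id)
    if (anyNA(idx)) {
      stopf("posterior for %s lacks imputations for population(s): %s", tr,
            paste(rownames(x)[miss][is.na(idx)], collapse = ", "))
    }
    x[miss, tr] <- imp$mean[idx]
  }
  if (restandardize) x <- scale(x)[, , drop = TRUE]
  attr(x, "meta") <- data[, c("species", "population_id", "region_sampled",
                              "native_region", "growth_form", "is_home")]
  x
}

#' Principal components analysis of a complete trait matrix
#'
#' Eigendecomposition of the covariance of the (centered) columns with
#' divisor n, the historical convention of base R's `princomp`. On Z-scaled
#' input this is the correlation structure. Components are ordered by
#' variance; the sign of each component is fixed so its largest-magnitude
#' loading is positive. Both raw eigenvalues and variance *shares*
#' (eigenvalue / total) are reported; with nine Z-scaled traits a share of
#' 0.27 corresponds to a raw eigenvalue near 2.4.
#'
#' @param x Complete numeric matrix (>= 2 rows and >= 2 columns, no `NA`).
#' @param ncomp Number of components to keep (default: all with positive
#'   eigenvalue; if fewer are available than requested, the result is
#'   truncated with a warning).
#' @param divisor `"n"` (default, `princomp`'s convention) or `"n-1"`
#'   (sample covariance); scales the eigenvalues but not the shares,
#'   loadings or score directions.
#' @return A `pca_result`: `loadings` (traits x components, orthonormal),
#'   `scores` (observations x components), `eigenvalues`, `shares`,
#'   `center`.
#' @export
run_pca <- function(x, ncomp = NULL, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  x <- as.matrix(x)
  if (anyNA(x)) stopf("matrix must be complete; impute missing cells first")
  if (nrow(x) < 2 || ncol(x) < 2) stopf("need at least 2 rows and 2 columns")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  n <- if (divisor == "n") nrow(x) else nrow(x) - 1
  cv <- crossprod(xc) / n
  e <- eigen(cv, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  pos <- sum(e$values > tol)
  keep <- if (is.null(ncomp)) pos else min(ncomp, pos)
  if (!is.null(ncomp) && keep < ncomp) {
    warnf("only %d components with positive eigenvalue; truncating from %d",
          pos, ncomp)
  }
  values <- e$values[seq_len(keep)]
  load <- e$vectors[, seq_len(keep), drop = FALSE]
  for (j in seq_len(keep)) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(keep)))
  scores <- xc %*% load
  structure(list(loadings = load, scores = scores, eigenvalues = values,
                 shares = e$values[seq_len(keep)] / sum(pmax(e$values, 0)),
                 center = ctr, meta = attr(x, "meta")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d components, variance shares %s\n",
              length(x$eigenvalues),
              paste(sprintf("%.2f", x$shares[seq_len(min(4, length(x$shares)))]),
                    collapse = ", ")))
  invisible(x)
}

#' Mixed model on principal component scores
#'
#' Tests whether a PC score differs between home and away populations:
#' fixed effects of home-away, native region and their interaction
#' (treatment contrasts, alphabetical reference region), plus a species
#' random intercept for within-species correlation, fit by REML via
#' `lmerTest::lmer`. A random-slope version is deliberately not offered
#' (it does not converge on data of this shape). Singular fits are
#' reported, not hidden.
#'
#' @param pca A `pca_result` from [run_pca()] on a matrix carrying a
#'   `"meta"` attribute (as produced by [impute_and_scale()]), or a numeric
#'   vector of scores if `meta` is supplied.
#' @param component Which component to analyze (default 1).
#' @param meta Observation metadata (`species`, `native_region`, `is_home`);
#'   taken from the PCA input when omitted.
#' @return A `pc_mixed_result`: fixed-effect table (estimate, SE, df, t, p),
#'   species and residual variances, singular flag, and the fitted model.
#' @export
fit_pc_mixed_model <- function(pca, component = 1, meta = NULL) {
  if (inherits(pca, "pca_result")) {
    scores <- pca$scores[, component]
    if (is.null(meta)) meta <- pca$meta
    if (is.null(meta)) {
      stopf("supply `meta` (species, native_region, is_home per observation)")
    }
  } else {
    scores <- as.numeric(pca)
    if (is.null(meta)) stopf("supply `meta` with the score vector")
  }
  stopifnot(nrow(meta) == length(scores))
  if (length(unique(meta$species)) < 2) {
    stopf("species random intercept inestimable: only one species")
  }
  if (!any(meta$is_home) || all(meta$is_home)) {
    stopf("both home and away observations are required")
  }
  df <- data.frame(score = scores,
                   home = factor(ifelse(meta$is_home, "home", "away"),
                                 levels = c("away", "home")),
                   native_region = factor(meta$native_region,
                                          levels = sort(unique(meta$native_region))),
                   species = meta$species)
  fm <- if (nlevels(df$native_region) > 1) {
    score ~ home * native_region + (1 | species)
  } else {
    score ~ home + (1 | species)
  }
  model <- lmerTest::lmer(fm, data = df, REML = TRUE)
  cf <- as.data.frame(stats::coef(summary(model)))
  names(cf) <- c("estimate", "se", "df", "t", "p")
  cf <- cbind(term = rownames(cf), cf)
  rownames(cf) <- NULL
  vc <- as.data.frame(lme4::VarCorr(model))
  structure(list(component = component,
                 fixed_effects = cf,
                 species_variance = vc$vcov[vc$grp == "species"],
                 residual_variance = vc$vcov[vc$grp == "Residual"],
                 singular = lme4::isSingular(model),
                 model = model),
            class = "pc_mixed_result")
}

#' @export
print.pc_mixed_result <- function(x, ...) {
  cat(sprintf("Mixed model on PC%d scores (species variance %.3f%s)\n",
              x$component, x$species_variance,
              if (x$singular) ", singular fit" else ""))
  print(x$fixed_effects, digits = 3)
  invisible(x)
}
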