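#' Specification of one hierarchical Bayesian home-away model
#'
#' One model per trait and growth form. The model, fit on Z-standardized
#' (log-scale) trait values, is
#' \deqn{Y_i ~ N(alpha_s + beta_r Home_i, sigma_Y^2)}
#' with species intercepts \eqn{alpha_s ~ N(0, sigma_S^2)} and home-away
#' effects per native region \eqn{beta_r ~ N(0, sigma_R^2)}; `Home` is 1
#' for populations sampled in the species' native region and 0 elsewhere,
#' so positive `beta` means larger values in the home range. All three SDs
#' carry uniform(0, `prior_sd_bound`) priors.
#'
#' @param trait One of the nine trait names.
#' @param growth_form `"woody"` or `"herbaceous"`.
#' @param chains Number of MCMC chains (>= 2; default 3).
#' @param iters Iterations per chain (default 5000).
#' @param burnin Burn-in iterations discarded per chain (default 500).
#' @param prior_sd_bound Upper bound of the uniform priors on SDs (default 100).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @return An `hb_model_spec`.
#' @export
hb_model_spec <- function(trait, growth_form = c("woody", "herbaceous"),
                          chains = 3L, iters = 5000L, burnin = 500L,
                          prior_sd_bound = 100, seed = 1L) {
  growth_form <- match.arg(growth_form)
  if (!trait %in% jtl_traits()) stopf("unknown trait '%s'", trait)
  if (chains < 2) stopf("at least 2 chains are required for convergence checks")
  if (iters <= burnin) stopf("iters must exceed burnin")
  if (prior_sd_bound <= 0) stopf("prior_sd_bound must be positive")
  structure(list(trait = trait, growth_form = growth_form,
                 chains = as.integer(chains), iters = as.integer(iters),
                 burnin = as.integer(burnin),
                 prior_sd_bound = prior_sd_bound, seed = as.integer(seed)),
            class = "hb_model_spec")
}

#' Fit the hierarchical home-away model by Gibbs sampling
#'
#' All full conditionals are conjugate: normal updates for the species
#' intercepts and region home-away effects, truncated-gamma updates for the
#' precisions under the uniform-on-SD priors (a bounded slice update when a
#' variance component has a single level), and normal draws for missing
#' trait values, which are carried as sampled quantities (posterior
#' imputation). The Gelman-Rubin statistic is computed for every scalar
#' parameter; if any exceeds 1.1 a convergence warning is issued and
#' recorded on the result, never silently dropped.
#'
#' For the cyanogenic glycoside model on woody species, *Prunus serotina*
#' is excluded by default (its values sit two orders of magnitude above all
#' other species in both ranges); pass `exclude_species = character()` to
#' keep it.
#'
#' @param tm A `trait_matrix` standardized within the model's growth form
#'   (see [z_standardize()]).
#' @param spec An [hb_model_spec()].
#' @param exclude_species Species dropped before fitting. `NULL` (default)
#'   applies the *P. serotina* rule above.
#' @param single_species_ok Allow fitting with a single species (used for
#'   reduced oracle checks); by default a single-species subset is an error
#'   because the species variance is inestimable.
#' @return An `hb_posterior` with draws, Gelman-Rubin statistics, posterior
#'   summaries, and the imputed-value draws.
#' @export
fit_home_away <- function(tm, spec, exclude_species = NULL,
                          single_species_ok = FALSE) {
  stopifnot(inherits(tm, "trait_matrix"), inherits(spec, "hb_model_spec"))
  data <- tm$data
  if (spec$growth_form %in% data$growth_form &&
      length(unique(data$growth_form)) > 1) {
    data <- data[data$growth_form == spec$growth_form, , drop = FALSE]
  }
  if (is.null(exclude_species)) {
    exclude_species <- if (spec$trait == "cyan" &&
                             spec$growth_form == "woody")
      "Prunus serotina" else character()
  }
  data <- data[!data$species %in% exclude_species, , drop = FALSE]
  if (nrow(data) == 0) stopf("no observations to fit")
  rec <- tm$transforms[[spec$trait]]
  if (is.na(rec$center)) {
    stopf("trait %s is not standardized; call z_standardize() first", spec$trait)
  }

  y <- data[[spec$trait]]
  species <- sort(unique(data$species))
  regions <- sort(unique(data$native_region))
  S <- length(species)
  R <- length(regions)
  if (S < 2 && !single_species_ok) {
    stopf("species random intercept inestimable: only %d species in subset", S)
  }
  home <- as.numeric(data$is_home)
  if (all(home == 1) || all(home == 0)) {
    stopf("home-away effect inestimable: all observations are %s",
          if (all(home == 1)) "home" else "away")
  }
  s_idx <- match(data$species, species)
  r_idx <- match(data$native_region, regions)
  n <- length(y)
  mis <- which(is.na(y))
  n_mis <- length(mis)

  n_s <- tabulate(s_idx, S)
  home_rows_by_r <- lapply(seq_len(R), function(r) which(r_idx == r & home == 1))
  n_home_r <- lengths(home_rows_by_r)

  n_keep <- spec$iters - spec$burnin
  bound <- spec$prior_sd_bound
  total <- n_keep * spec$chains
  d_alpha <- matrix(NA_real_, total, S, dimnames = list(NULL, species))
  d_beta <- matrix(NA_real_, total, R, dimnames = list(NULL, regions))
  d_sigma <- matrix(NA_real_, total, 3,
                    dimnames = list(NULL, c("sigma_y", "sigma_s", "sigma_r")))
  d_ymis <- if (n_mis) matrix(NA_real_, total, n_mis,
                              dimnames = list(NULL, data$population_id[mis]))
            else matrix(NA_real_, total, 0)
  chain_id <- rep(seq_len(spec$chains), each = n_keep)

  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + ch)
    yy <- y
    if (n_mis) yy[mis] <- 0
    alpha <- rep(0, S)
    beta <- rep(0, R)
    sig_y <- 1; sig_s <- 1; sig_r <- 1
    row0 <- (ch - 1L) * n_keep
    for (it in seq_len(spec$iters)) {
      bh <- beta[r_idx] * home
      # species intercepts
      resid <- yy - bh
      prec <- n_s / sig_y^2 + 1 / sig_s^2
      mu <- (rowsum(resid, s_idx)[, 1] / sig_y^2) / prec
      alpha <- stats::rnorm(S, mu, sqrt(1 / prec))
      # home-away effects per native region (only home rows inform beta)
      resid <- yy - alpha[s_idx]
      sums_r <- vapply(home_rows_by_r, function(ix) sum(resid[ix]), 0.0)
      prec_r <- n_home_r / sig_y^2 + 1 / sig_r^2
      beta <- stats::rnorm(R, (sums_r / sig_y^2) / prec_r, sqrt(1 / prec_r))
      # missing values as sampled quantities
      mu_full <- alpha[s_idx] + beta[r_idx] * home
      if (n_mis) yy[mis] <- stats::rnorm(n_mis, mu_full[mis], sig_y)
      # variance components
      sig_y <- draw_sigma(n, sum((yy - mu_full)^2), bound, sig_y)
      sig_s <- draw_sigma(S, sum(alpha^2), bound, sig_s)
      sig_r <- draw_sigma(R, sum(beta^2), bound, sig_r)
      if (it > spec$burnin) {
        k <- row0 + it - spec$burnin
        d_alpha[k, ] <- alpha
        d_beta[k, ] <- beta
        d_sigma[k, ] <- c(sig_y, sig_s, sig_r)
        if (n_mis) d_ymis[k, ] <- yy[mis]
      }
    }
  }

  draws <- cbind(d_alpha, d_beta, d_sigma)
  colnames(draws) <- c(paste0("alpha[", species, "]"),
                       paste0("beta[", regions, "]"),
                       colnames(d_sigma))
  rhat <- vapply(seq_len(ncol(draws)), function(j) {
    gelman_rubin(matrix(draws[, j], n_keep, spec$chains))
  }, 0.0)
  names(rhat) <- colnames(draws)
  convergence_ok <- all(is.finite(rhat)) && max(rhat) <= 1.1
  if (!convergence_ok) {
    warnf("Gelman-Rubin diagnostic above 1.1 for: %s",
          paste(names(rhat)[!is.finite(rhat) | rhat > 1.1], collapse = ", "))
  }
  qs <- function(m) {
    t(apply(m, 2, function(v) c(mean = mean(v), sd = stats::sd(v),
                                lower = unname(stats::quantile(v, 0.025)),
                                upper = unname(stats::quantile(v, 0.975)))))
  }
  summ <- as.data.frame(qs(draws))
  summ$rhat <- rhat
  summ <- cbind(parameter = rownames(summ), summ)
  rownames(summ) <- NULL

  structure(list(spec = spec,
                 draws = list(alpha = d_alpha, beta = d_beta,
                              sigma = d_sigma, y_mis = d_ymis),
                 chain = chain_id,
                 n_keep = n_keep,
                 data = list(y = y, species = species, regions = regions,
                             s_idx = s_idx, r_idx = r_idx, home = home,
                             population_id = data$population_id,
                             species_of_obs = data$species,
                             missing_idx = mis),
                 transform = rec,
                 rhat = rhat,
                 summary = summ,
                 convergence_ok = convergence_ok),
            class = "hb_posterior")
}

#' @export
print.hb_posterior <- function(x, ...) {
  cat(sprintf("Hierarchical home-away model: trait '%s', %s species\n",
              x$spec$trait, x$spec$growth_form))
  cat(sprintf("  %d obs (%d imputed), %d species, chains %d x %d kept draws\n",
              length(x$data$y), length(x$data$missing_idx),
              length(x$data$species), x$spec$chains, x$n_keep))
  cat(sprintf("  max Gelman-Rubin = %.3f (%s)\n", max(x$rhat),
              if (x$convergence_ok) "converged" else "NOT converged"))
  b <- x$summary[grepl("^beta", x$summary$parameter), ]
  cat("  home-away effects (positive = larger at home):\n")
  for (i in seq_len(nrow(b))) {
    cat(sprintf("    %s: %+.3f [%+.3f, %+.3f]\n", b$parameter[i],
                b$mean[i], b$lower[i], b$upper[i]))
  }
  invisible(x)
}

#' Home-away shift summaries on the away-minus-home scale
#'
#' The model codes `Home` as 1, so `beta` is home-minus-away; plots and
#' reports often use the opposite sign (positive = larger trait values in
#' the away range). This accessor returns both conventions.
#'
#' @param fit An `hb_posterior`.
#' @return Data frame with one row per native region: posterior mean and
#'   95% credible interval of `beta` (home-minus-away) and of `shift`
#'   (away-minus-home, the negated effect).
#' @export
home_away_shift <- function(fit) {
  stopifnot(inherits(fit, "hb_posterior"))
  b <- fit$draws$beta
  out <- data.frame(native_region = colnames(b),
                    beta_mean = colMeans(b),
                    beta_lower = apply(b, 2, stats::quantile, 0.025),
                    beta_upper = apply(b, 2, stats::quantile, 0.975))
  out$shift_mean <- -out$beta_mean
  out$shift_lower <- -out$beta_upper
  out$shift_upper <- -out$beta_lower
  rownames(out) <- NULL
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain diagnostic for one scalar parameter:
#' with m chains of n draws, within-chain variance W = mean of the chain
#' variances, between-chain variance B = n * var(chain means), and
#' \deqn{ \hat R = \sqrt{ ((n-1)/n W + B/n) / W }. }
#' Values near 1 indicate the chains are sampling the same distribution.
#'
#' @param draws An n x m matrix (rows = iterations, columns = chains), or a
#'   list of equal-length numeric chains.
#' @return The potential scale reduction factor. If every chain is constant
#'   at the same value, 1 by convention; constant chains at different
#'   values give `Inf`.
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  m <- ncol(draws)
  n <- nrow(draws)
  if (m < 2) stopf("Gelman-Rubin requires at least 2 chains")
  if (n < 2) stopf("Gelman-Rubin requires at least 2 draws per chain")
  w <- mean(apply(draws, 2, stats::var))
  b_over_n <- stats::var(colMeans(draws))
  if (w == 0) return(if (b_over_n == 0) 1 else Inf)
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Bayesian marginal and conditional R-squared
#'
#' Per posterior draw, R2 = var(linear predictor) / (var(linear predictor)
#' + sigma_Y^2), with the variance taken over observations. The marginal
#' version uses only the home-away structure (mu = beta * Home); the
#' conditional version adds the species intercepts (mu = alpha + beta *
#' Home). Posterior medians are reported.
#'
#' @param fit An `hb_posterior`.
#' @return An `r2_pair`: list with `marginal`, `conditional` (posterior
#'   medians) and `draws` (per-draw values).
#' @export
bayes_r2 <- function(fit) {
  stopifnot(inherits(fit, "hb_posterior"))
  d <- fit$data
  ndraw <- nrow(fit$draws$beta)
  r2m <- numeric(ndraw)
  r2c <- numeric(ndraw)
  for (k in seq_len(ndraw)) {
    mu_m <- fit$draws$beta[k, d$r_idx] * d$home
    mu_c <- fit$draws$alpha[k, d$s_idx] + mu_m
    s2 <- fit$draws$sigma[k, "sigma_y"]^2
    vm <- stats::var(mu_m)
    vc <- stats::var(mu_c)
    r2m[k] <- vm / (vm + s2)
    r2c[k] <- vc / (vc + s2)
  }
  structure(list(marginal = stats::median(r2m),
                 conditional = stats::median(r2c),
                 draws = data.frame(marginal = r2m, conditional = r2c)),
            class = "r2_pair")
}

#' @export
print.r2_pair <- function(x, ...) {
  cat(sprintf("Bayesian R2: marginal %.3f, conditional %.3f\n",
              x$marginal, x$conditional))
  invisible(x)
}

#' Posterior-mean imputations for missing trait values
#'
#' One posterior mean and 95% credible interval per missing cell, on the
#' standardized scale the model was fit on, plus the back-transformed
#' raw-scale mean through the stored transform record.
#'
#' @param fit An `hb_posterior`.
#' @param population_id Optional subset of population IDs; requesting a
#'   population whose value was observed is an error.
#' @return Data frame keyed by population and species with columns `mean`,
#'   `lower`, `upper` (standardized scale) and `raw_mean`.
#' @export
impute_missing <- function(fit, population_id = NULL) {
  stopifnot(inherits(fit, "hb_posterior"))
  mis <- fit$data$missing_idx
  out <- data.frame(population_id = fit$data$population_id[mis],
                    species = fit$data$species_of_obs[mis],
                    trait = rep(fit$spec$trait, length(mis)),
                    stringsAsFactors = FALSE)
  if (length(mis)) {
    ym <- fit$draws$y_mis
    out$mean <- colMeans(ym)
    out$lower <- apply(ym, 2, stats::quantile, 0.025)
    out$upper <- apply(ym, 2, stats::quantile, 0.975)
  } else {
    out$mean <- numeric(0); out$lower <- numeric(0); out$upper <- numeric(0)
  }
  if (!is.null(population_id)) {
    observed <- setdiff(population_id, out$population_id)
    observed <- intersect(observed, fit$data$population_id)
    if (length(observed)) {
      stopf("value(s) observed, not missing, for population(s): %s",
            paste(observed, collapse = ", "))
    }
    unknown <- setdiff(population_id, fit$data$population_id)
    if (length(unknown)) {
      stopf("unknown population(s): %s", paste(unknown, collapse = ", "))
    }
    out <- out[out$population_id %in% population_id, , drop = FALSE]
  }
  rec <- fit$transform
  z2raw <- function(z) {
    v <- z * rec$scale + rec$center
    if (rec$log) exp(v) else v
  }
  out$raw_mean <- if (nrow(out)) z2raw(out$mean) else numeric(0)
  rownames(out) <- NULL
  out
}

#' Export posterior summaries
#'
#' Writes the per-parameter posterior summary (mean, 2.5%, 97.5%,
#' Gelman-Rubin) as CSV or JSON.
#'
#' @param fit An `hb_posterior`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
export_posterior <- function(fit, path) {
  stopifnot(inherits(fit, "hb_posterior"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(fit$summary, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(fit$summary, path, row.names = FALSE)
  }
  invisible(path)
}
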