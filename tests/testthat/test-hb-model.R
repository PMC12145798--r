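test_that("Gelman-Rubin matches the between/within formula and its conventions", {
  set.seed(1)
  n <- 1000
  mixed <- cbind(rnorm(n), rnorm(n, 5), rnorm(n, -5))
  w <- mean(apply(mixed, 2, var))
  b_over_n <- var(colMeans(mixed))
  expect_equal(gelman_rubin(mixed),
               sqrt(((n - 1) / n * w + b_over_n) / w), tolerance = 1e-10)

  set.seed(2)
  two <- cbind(rnorm(1000), rnorm(1000, 5))
  w2 <- mean(apply(two, 2, var))
  b2 <- var(colMeans(two))
  expect_equal(gelman_rubin(two),
               sqrt(((1000 - 1) / 1000 * w2 + b2) / w2), tolerance = 1e-10)
  expect_gt(gelman_rubin(two), 2)  # clearly unmixed

  set.seed(3)
  same <- matrix(rnorm(15000), 5000, 3)
  expect_lt(gelman_rubin(same), 1.05)

  expect_identical(gelman_rubin(matrix(2, 10, 3)), 1)
  expect_identical(gelman_rubin(cbind(rep(1, 10), rep(2, 10))), Inf)
  expect_error(gelman_rubin(matrix(rnorm(10), 10, 1)), "2 chains")
})

test_that("collapsed one-species model recovers the OLS home coefficient", {
  set.seed(42)
  n <- 120
  home <- rep(c(1, 0), each = n / 2)
  y <- 0.4 + 0.8 * home + rnorm(n, 0, 1)
  tm <- make_tm(species = rep("Solo", n), native_region = rep("Japan", n),
                is_home = home == 1, y = y)
  fit <- fit_home_away(tm, hb_model_spec("sla", "woody", iters = 4000,
                                         burnin = 500, seed = 9),
                       single_species_ok = TRUE)
  ols <- mean(y[home == 1]) - mean(y[home == 0])
  beta_draws <- fit$draws$beta[, "Japan"]
  mcse <- jointhelocals:::mcse_mean(beta_draws)
  expect_lt(abs(mean(beta_draws) - ols), 3 * mcse + 0.02)
})

test_that("single-species subsets error unless explicitly allowed", {
  tm <- make_tm(species = rep("Solo", 10), native_region = rep("Japan", 10),
                is_home = rep(c(TRUE, FALSE), 5), y = rnorm(10))
  expect_error(fit_home_away(tm, hb_model_spec("sla", "woody", iters = 600,
                                               burnin = 100)),
               "only 1 species")
})

test_that("all-home or all-away data make the home-away effect inestimable", {
  tm <- make_tm(species = rep(c("A", "B"), each = 5),
                native_region = rep("Japan", 10),
                is_home = rep(TRUE, 10), y = rnorm(10))
  expect_error(fit_home_away(tm, hb_model_spec("sla", "woody", iters = 600,
                                               burnin = 100)), "all observations")
})

test_that("SD draws respect the uniform prior support", {
  gen <- generate_traits(scenario_presets("null", seed = 8))
  tm <- z_standardize(log_transform(gen$table), subset = "herbaceous")
  fit <- fit_home_away(tm, hb_model_spec("cn", "herbaceous", iters = 1200,
                                         burnin = 200, seed = 2))
  expect_true(all(fit$draws$sigma > 0))
  expect_true(all(fit$draws$sigma <= 100))
  expect_identical(nrow(fit$draws$beta), 3L * 1000L)
})

test_that("complete data produce an empty imputation set; observed cells error", {
  cfg <- synthetic_config(missing_rate = 0, seed = 5)
  gen <- generate_traits(cfg)
  tm <- z_standardize(log_transform(gen$table), subset = "woody")
  fit <- fit_home_away(tm, hb_model_spec("fiber", "woody", iters = 800,
                                         burnin = 200, seed = 3))
  imp <- impute_missing(fit)
  expect_identical(nrow(imp), 0L)
  some_obs <- fit$data$population_id[1]
  expect_error(impute_missing(fit, population_id = some_obs), "observed")
  expect_error(impute_missing(fit, population_id = "no_such_pop"), "unknown")
})

test_that("imputations shrink toward the species mean, with honest uncertainty", {
  set.seed(7)
  n_sp <- 8
  pops <- 10
  species <- rep(sprintf("Sp%02d", seq_len(n_sp)), each = pops)
  alpha <- c(1, rnorm(n_sp - 2, 0, 0.5), 0)
  home <- rep(rep(c(TRUE, FALSE), each = pops / 2), n_sp)
  y <- alpha[match(species, unique(species))] + rnorm(n_sp * pops, 0, 0.3)
  y[1] <- NA                                   # one missing cell for Sp01 (alpha = +1)
  y[species == "Sp08"] <- NA                   # an entirely unobserved species
  # pin the observed Sp01 mean at its intercept so the check isolates shrinkage
  obs1 <- which(species == "Sp01" & !is.na(y))
  y[obs1] <- y[obs1] - mean(y[obs1]) + 1
  native <- rep(rep(c("Japan", "USA"), length.out = n_sp), each = pops)
  tm <- make_tm(species, native, home, y)
  fit <- fit_home_away(tm, hb_model_spec("sla", "woody", iters = 3000,
                                         burnin = 500, seed = 11))
  imp <- impute_missing(fit)
  one <- imp[imp$population_id == "pop001", ]
  expect_equal(nrow(one), 1L)
  expect_lt(abs(one$mean - 1), 0.3)
  ghost <- imp[imp$species == "Sp08", ]
  # no data: centered near the species-level prior mean, wide intervals
  expect_lt(abs(mean(ghost$mean)), 0.45)
  expect_gt(mean(ghost$upper - ghost$lower), one$upper - one$lower)
})

test_that("Bayesian R2 behaves in the noiseless, null and species-dominated regimes", {
  # near-noiseless: conditional R2 -> 1
  set.seed(20)
  n_sp <- 6; pops <- 8
  species <- rep(sprintf("S%d", 1:n_sp), each = pops)
  alpha <- rnorm(n_sp, 0, 1)
  home <- rep(rep(c(TRUE, FALSE), each = pops / 2), n_sp)
  y <- alpha[match(species, unique(species))] + 0.5 * home +
    rnorm(n_sp * pops, 0, 1e-4)
  tm <- make_tm(species, rep("Japan", n_sp * pops), home, y)
  fit <- fit_home_away(tm, hb_model_spec("sla", "woody", iters = 1500,
                                         burnin = 300, seed = 5))
  r2 <- bayes_r2(fit)
  expect_gt(r2$conditional, 0.99)

  # null data: marginal R2 near zero
  gen <- generate_traits(synthetic_config(sigma_s = 0.5, sigma_y = 0.5,
                                          missing_rate = 0, seed = 19))
  tmn <- z_standardize(log_transform(gen$table), subset = "woody")
  fitn <- fit_home_away(tmn, hb_model_spec("sla", "woody", iters = 1200,
                                           burnin = 200, seed = 6))
  r2n <- bayes_r2(fitn)
  expect_lt(r2n$marginal, 0.05)
  # species effects absorb variance: conditional exceeds marginal
  expect_gt(r2n$conditional, r2n$marginal)
})

test_that("the Gibbs sampler agrees with an independent JAGS fit", {
  skip_if_not_installed("rjags")
  gen <- generate_traits(synthetic_config(
    design = mini_design(per_region = 3, pops = 5),
    beta_means = matrix(rep(c(0.5, 0, -0.5), each = 9), 9, 3),
    sigma_s = 0.5, sigma_y = 0.4, missing_rate = 0, seed = 23))
  tm <- z_standardize(log_transform(gen$table), subset = "woody")
  fit <- fit_home_away(tm, hb_model_spec("sla", "woody", iters = 6000,
                                         burnin = 1000, seed = 3))

  d <- tm$data
  model_str <- "model {
    for (i in 1:n) { y[i] ~ dnorm(alpha[s[i]] + beta[r[i]] * home[i], tau_y) }
    for (k in 1:S) { alpha[k] ~ dnorm(0, tau_s) }
    for (k in 1:R) { beta[k] ~ dnorm(0, tau_r) }
    sig_y ~ dunif(0, 100); tau_y <- pow(sig_y, -2)
    sig_s ~ dunif(0, 100); tau_s <- pow(sig_s, -2)
    sig_r ~ dunif(0, 100); tau_r <- pow(sig_r, -2)
  }"
  species <- sort(unique(d$species))
  regions <- sort(unique(d$native_region))
  jd <- list(y = d$sla, s = match(d$species, species),
             r = match(d$native_region, regions),
             home = as.numeric(d$is_home), n = nrow(d),
             S = length(species), R = length(regions))
  jm <- rjags::jags.model(textConnection(model_str), data = jd, n.chains = 3,
                          quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 7))
  update(jm, 1000, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("beta", "sig_y"), n.iter = 5000,
                              progress.bar = "none")
  jags_means <- colMeans(do.call(rbind, lapply(samp, as.matrix)))
  ours <- colMeans(fit$draws$beta)
  expect_lt(max(abs(ours - jags_means[paste0("beta[", 1:3, "]")])), 0.08)
  expect_lt(abs(mean(fit$draws$sigma[, "sigma_y"]) - jags_means["sig_y"]), 0.04)
})
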