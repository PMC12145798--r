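# End-to-end orchestration: data -> transforms -> hierarchical fits ->
# imputation -> PCA/mixed models -> join-the-locals tests -> regional
# tables, with per-stage seeds and a manifest.

#' Pipeline configuration
#'
#' Either `input` (a trait-table CSV) or `scenario` (a synthetic preset
#' name) must be given. A single `seed` fans out to fixed per-stage seeds
#' (see [stage_seed()]) so any stage can be re-run in isolation with
#' identical output.
#'
#' @param input Path to a trait-table CSV, or `NULL`.
#' @param scenario Synthetic scenario (`"enemy_release"`,
#'   `"join_the_locals"`, `"null"`), or `NULL`.
#' @param traits Traits to analyze (default all nine).
#' @param growth_forms Growth forms to analyze (default both).
#' @param chains,iters,burnin MCMC settings (see [hb_model_spec()]).
#' @param boot_B Bootstrap resamples for the join-the-locals test.
#' @param jtlh_scale Scale for contrasts: `"transformed"` or `"raw"`.
#' @param seed Master seed.
#' @param out_dir Output directory (created if absent).
#' @param keep_going Continue past stage errors (default `FALSE`).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, scenario = NULL,
                            traits = jtl_traits(),
                            growth_forms = c("woody", "herbaceous"),
                            chains = 3L, iters = 5000L, burnin = 500L,
                            boot_B = 1000L, jtlh_scale = "transformed",
                            seed = 1L, out_dir = tempfile("jtl_run_"),
                            keep_going = FALSE) {
  if (is.null(input) && is.null(scenario)) {
    stopf("either `input` or `scenario` must be supplied")
  }
  if (!is.null(input) && !file.exists(input)) {
    stopf("input file not found: %s", input)
  }
  stopifnot(all(traits %in% jtl_traits()),
            all(growth_forms %in% growth_forms()))
  structure(list(input = input, scenario = scenario, traits = traits,
                 growth_forms = growth_forms, chains = as.integer(chains),
                 iters = as.integer(iters), burnin = as.integer(burnin),
                 boot_B = as.integer(boot_B), jtlh_scale = jtlh_scale,
                 seed = as.integer(seed), out_dir = out_dir,
                 keep_going = isTRUE(keep_going)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

run_stage <- function(config, stage, expr) {
  tryCatch(expr, error = function(e) {
    msg <- sprintf("stage '%s' failed: %s", stage, conditionMessage(e))
    if (config$keep_going) {
      warnf("%s (continuing)", msg)
      NULL
    } else {
      stopf("%s", msg)
    }
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the trait table; log/Z transforms;
#' hierarchical home-away fits per trait and growth form (posterior
#' summary CSVs); posterior-mean imputation, PCA and PC-score mixed models
#' per growth form; join-the-locals contrast tables and bootstrap tests
#' per trait; regional ANOVA tables for traits and environment covariates
#' plus woody-vs-herbaceous Welch tests; and a JSON manifest recording the
#' package version, seeds, input hash and outputs. Re-running with the
#' same configuration reproduces every result file byte for byte.
#'
#' @param config A [pipeline_config()] or path to a YAML config file.
#' @return Invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  # --- data ---------------------------------------------------------------
  data_res <- run_stage(config, "data", {
    if (!is.null(config$input)) {
      list(table = read_trait_table(config$input), source = config$input)
    } else {
      cfg <- scenario_presets(config$scenario,
                              seed = stage_seed(config$seed, "simulate"))
      gen <- generate_traits(cfg)
      list(table = gen$table, truth = gen$truth, source = config$scenario)
    }
  })
  if (is.null(data_res)) stopf("stage 'data' produced nothing; cannot continue")
  table <- data_res$table
  write_trait_table(table, out("trait_table.csv"))

  # --- hierarchical fits ----------------------------------------------------
  posteriors <- list()
  hb_rows <- list()
  for (gf in config$growth_forms) {
    tm <- run_stage(config, paste0("transform_", gf),
                    z_standardize(log_transform(table), subset = gf))
    if (is.null(tm)) next
    posteriors[[gf]] <- list()
    for (tr in config$traits) {
      fit <- run_stage(config, sprintf("hb_%s_%s", gf, tr), {
        spec <- hb_model_spec(tr, gf, chains = config$chains,
                              iters = config$iters, burnin = config$burnin,
                              seed = stage_seed(config$seed,
                                                paste0("hb_", gf, "_", tr)))
        fit_home_away(tm, spec)
      })
      if (is.null(fit)) next
      posteriors[[gf]][[tr]] <- fit
      r2 <- bayes_r2(fit)
      sh <- home_away_shift(fit)
      sh <- cbind(trait = tr, growth_form = gf, sh,
                  marginal_r2 = r2$marginal, conditional_r2 = r2$conditional,
                  max_rhat = max(fit$rhat))
      hb_rows[[length(hb_rows) + 1L]] <- sh
      export_posterior(fit, out(sprintf("hb_%s_%s.csv", gf, tr)))
    }
  }
  if (length(hb_rows)) {
    utils::write.csv(do.call(rbind, hb_rows), out("hb_shifts.csv"),
                     row.names = FALSE)
  }

  # --- multivariate ---------------------------------------------------------
  pca_results <- list()
  for (gf in if (length(config$traits) >= 2) config$growth_forms else character()) {
    res <- run_stage(config, paste0("pca_", gf), {
      x <- impute_and_scale(table, posteriors[[gf]], growth_form = gf,
                            traits = config$traits)
      pca <- run_pca(x)
      mm <- lapply(1:2, function(k) fit_pc_mixed_model(pca, component = k))
      utils::write.csv(data.frame(trait = rownames(pca$loadings),
                                  pca$loadings[, 1:min(4, ncol(pca$loadings))]),
                       out(sprintf("pca_%s_loadings.csv", gf)),
                       row.names = FALSE)
      utils::write.csv(data.frame(pca$meta, pca$scores[, 1:2]),
                       out(sprintf("pca_%s_scores.csv", gf)),
                       row.names = FALSE)
      jsonlite::write_json(
        list(shares = pca$shares, eigenvalues = pca$eigenvalues,
             mixed_models = lapply(mm, function(m)
               list(component = m$component, fixed_effects = m$fixed_effects,
                    species_variance = m$species_variance,
                    residual_variance = m$residual_variance,
                    singular = m$singular))),
        out(sprintf("pca_%s_summary.json", gf)),
        dataframe = "rows", auto_unbox = TRUE, digits = NA)
      list(pca = pca, mixed = mm)
    })
    if (!is.null(res)) pca_results[[gf]] <- res
  }

  # --- join the locals ------------------------------------------------------
  jtlh_results <- list()
  jtlh_rows <- list()
  for (tr in config$traits) {
    res <- run_stage(config, paste0("jtlh_", tr), {
      ct <- build_contrast_table(table, tr, scale = config$jtlh_scale)
      test <- bootstrap_slope_test(ct, B = config$boot_B,
                                   seed = stage_seed(config$seed,
                                                     paste0("jtlh_", tr)))
      utils::write.csv(ct, out(sprintf("contrasts_%s.csv", tr)),
                       row.names = FALSE)
      list(contrasts = ct, test = test)
    })
    if (is.null(res)) next
    jtlh_results[[tr]] <- res
    jtlh_rows[[length(jtlh_rows) + 1L]] <- data.frame(
      trait = tr, n_contrasts = res$test$n_contrasts,
      slope = res$test$slope, intercept = res$test$intercept,
      r_squared = res$test$r_squared, p_value = res$test$p_value)
  }
  if (length(jtlh_rows)) {
    utils::write.csv(do.call(rbind, jtlh_rows), out("jtlh_results.csv"),
                     row.names = FALSE)
  }

  # --- regional descriptive tables -------------------------------------------
  describe <- run_stage(config, "describe", {
    vars <- c(config$traits, jtl_env_vars())
    rows <- list()
    anovas <- list()
    for (v in vars) {
      a <- tryCatch(region_anova(table, v), error = function(e) NULL)
      if (is.null(a)) next
      anovas[[v]] <- a
      wide <- stats::setNames(
        as.list(sprintf("%.4g +/- %.3g%s", a$means$mean, a$means$se,
                        a$means$letters)), a$means$region)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, as.data.frame(wide), df1 = a$df[1], df2 = a$df[2],
        f = a$f, p_value = a$p_value)
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, out("region_tables.csv"), row.names = FALSE)
    wt <- lapply(config$traits, function(tr) {
      w <- table[[tr]][table$growth_form == "woody"]
      h <- table[[tr]][table$growth_form == "herbaceous"]
      if (sum(!is.na(w)) < 2 || sum(!is.na(h)) < 2) return(NULL)
      t <- welch_ttest(w, h)
      data.frame(trait = tr, mean_woody = t$mean_a, mean_herbaceous = t$mean_b,
                 t = t$t, df = t$df, p_value = t$p_value)
    })
    wt <- do.call(rbind, wt)
    utils::write.csv(wt, out("growth_form_ttests.csv"), row.names = FALSE)
    list(anovas = anovas, region_table = tab, growth_form_tests = wt)
  })

  # --- manifest ---------------------------------------------------------------
  manifest <- list(
    package = "jointhelocals",
    version = as.character(utils::packageVersion("jointhelocals")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    source = data_res$source,
    input_md5 = if (!is.null(config$input))
      unname(tools::md5sum(config$input)) else NA,
    seed = config$seed,
    stage_seeds = list(
      simulate = stage_seed(config$seed, "simulate"),
      jtlh = stats::setNames(
        lapply(config$traits, function(tr) stage_seed(config$seed,
                                                      paste0("jtlh_", tr))),
        config$traits)),
    config = config[setdiff(names(config), "out_dir")],
    outputs = sort(list.files(config$out_dir)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(table = table, posteriors = posteriors, pca = pca_results,
                 jtlh = jtlh_results, describe = describe,
                 manifest = manifest, out_dir = config$out_dir))
}
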