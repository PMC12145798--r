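#' Long-format trait tables for home-away comparisons
#'
#' The universal input of the package: one row per sampled population with
#' the species identity, the region where it was sampled, the species' native
#' region, growth form, nine leaf defense traits and four environment
#' covariates. Trait cells may be missing (`NA`); zeros are valid only for
#' the two assay-floor traits (cyanogenic glycosides, alkaloids).
#'
#' Required columns: `species`, `population_id`, `region_sampled`,
#' `native_region`, `growth_form`, `is_home`, the nine traits `cyan`,
#' `alkaloids`, `fiber`, `cell_wall`, `protein`, `cn`, `c_mass`, `n_mass`,
#' `sla`, and the environment covariates `soil_ph`, `gli`, `mat`, `map`.
#'
#' @param df A data.frame with the columns above.
#' @return A validated `trait_table` (a data.frame subclass).
#' @export
trait_table <- function(df) {
  errs <- validate_trait_table(df)
  if (length(errs)) {
    stopf("invalid trait table:\n%s", paste(errs, collapse = "\n"))
  }
  df$species <- as.character(df$species)
  df$population_id <- as.character(df$population_id)
  df$is_home <- as.logical(df$is_home)
  class(df) <- unique(c("trait_table", class(df)))
  df
}

required_trait_columns <- function() {
  c("species", "population_id", "region_sampled", "native_region",
    "growth_form", "is_home", jtl_traits(), jtl_env_vars())
}

#' Validate a candidate trait table
#'
#' Checks the schema and per-row invariants: region and growth-form labels
#' come from the study's closed vocabularies, present trait values are
#' strictly positive (zero permitted only for cyanogenic glycosides and
#' alkaloids), percentage traits and GLI lie in \[0, 100\], and the `is_home`
#' flag agrees with `region_sampled == native_region`.
#'
#' @param df A data.frame.
#' @return Character vector of row-indexed problem messages (empty if valid).
#' @export
validate_trait_table <- function(df) {
  if (!is.data.frame(df)) return("input is not a data.frame")
  missing_cols <- setdiff(required_trait_columns(), names(df))
  if (length(missing_cols)) {
    return(sprintf("missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) return("trait table is empty")
  errs <- character()
  bad <- function(rows, fmt, ...) {
    if (any(rows)) {
      sprintf("row %d: %s", which(rows), sprintf(fmt, ...))
    } else character()
  }
  errs <- c(errs, bad(!(df$region_sampled %in% jtl_regions()),
                      "unknown region_sampled label"))
  errs <- c(errs, bad(!(df$native_region %in% jtl_regions()),
                      "unknown native_region label"))
  errs <- c(errs, bad(!(df$growth_form %in% growth_forms()),
                      "unknown growth_form label"))
  for (tr in jtl_traits()) {
    v <- df[[tr]]
    if (!is.numeric(v)) {
      errs <- c(errs, sprintf("column %s is not numeric", tr))
      next
    }
    if (tr %in% zero_ok_traits()) {
      errs <- c(errs, bad(!is.na(v) & v < 0, "%s is negative", tr))
    } else {
      errs <- c(errs, bad(!is.na(v) & v <= 0, "%s is not strictly positive", tr))
    }
    if (tr %in% percent_traits()) {
      errs <- c(errs, bad(!is.na(v) & (v < 0 | v > 100),
                          "%s outside [0, 100]", tr))
    }
  }
  if (is.numeric(df$gli)) {
    errs <- c(errs, bad(!is.na(df$gli) & (df$gli < 0 | df$gli > 100),
                        "gli outside [0, 100]"))
  }
  ok_regions <- df$region_sampled %in% jtl_regions() &
    df$native_region %in% jtl_regions()
  derived <- df$region_sampled == df$native_region
  errs <- c(errs, bad(ok_regions & !is.na(df$is_home) &
                        as.logical(df$is_home) != derived,
                      "is_home disagrees with region_sampled/native_region"))
  errs
}

#' Read a trait table from CSV
#'
#' Comma-separated UTF-8 with a header row; missing values are empty cells
#' or `"NA"`. Rows violating the invariants are reported with their row
#' numbers and the read fails.
#'
#' @param path Path to a CSV file.
#' @return A validated [trait_table()].
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (nrow(df) == 0) stopf("empty trait table file: %s", path)
  trait_table(df)
}

#' Write a trait table to CSV
#'
#' Inverse of [read_trait_table()]: the round trip is lossless, including
#' the missingness pattern (missing cells are written as empty fields).
#'
#' @param x A `trait_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  stopifnot(inherits(x, "trait_table"))
  utils::write.csv(as.data.frame(x)[, required_trait_columns()], path,
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a study design (species x region sampling plan)
#'
#' By default loads the packaged 44-species, three-region design replica:
#' per species its family, growth form, native region(s), the regions where
#' it is invasive, and the number of populations sampled per region.
#'
#' @param path CSV path; `NULL` (default) loads the packaged design.
#' @return A `study_design` data.frame with list-columns `native_regions`
#'   and `invasive_in`, logical `is_invasive`, and a `native_primary` column
#'   (first-listed native region, used wherever a single region is needed).
#' @export
read_study_design <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_design.csv",
                        package = "jointhelocals", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  need <- c("species", "family", "growth_form", "native_to", "invasive_in",
            "pops_france", "pops_japan", "pops_usa")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("design is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$species)) stopf("species names must be unique")
  pops <- as.matrix(df[, c("pops_france", "pops_japan", "pops_usa")])
  if (any(is.na(pops)) || any(pops < 0) || any(pops != round(pops))) {
    stopf("populations sampled must be non-negative integers")
  }
  df$native_regions <- strsplit(df$native_to, "/", fixed = TRUE)
  bad_nat <- !vapply(df$native_regions,
                     function(r) all(r %in% jtl_regions()), TRUE)
  if (any(bad_nat)) {
    stopf("unknown native region for species: %s",
          paste(df$species[bad_nat], collapse = ", "))
  }
  df$native_primary <- vapply(df$native_regions, `[`, "", 1)
  df$invasive_in <- lapply(df$invasive_in, function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, "/", fixed = TRUE)[[1]]
  })
  df$is_invasive <- lengths(df$invasive_in) > 0
  if (!all(df$growth_form %in% growth_forms())) stopf("unknown growth form in design")
  class(df) <- unique(c("study_design", class(df)))
  df
}

design_pops <- function(design, region) {
  col <- c(France = "pops_france", Japan = "pops_japan", USA = "pops_usa")[[region]]
  design[[col]]
}

#' Summarize a study design
#'
#' Returns the headline counts of the sampling plan and the list of
#' invader-by-away-region contrasts: one contrast per (invasive species,
#' region) pair where the species was sampled in a region outside its
#' native range.
#'
#' @param design A `study_design` from [read_study_design()].
#' @return A list with `n_species`, `n_woody`, `n_herbaceous`, `n_invasive`,
#'   a `contrasts` data.frame (`species`, `native_region`, `away_region`,
#'   `growth_form`) and `n_contrasts`.
#' @export
design_summary <- function(design) {
  stopifnot(inherits(design, "study_design"))
  contrasts <- list()
  for (i in seq_len(nrow(design))) {
    if (!design$is_invasive[i]) next
    for (region in jtl_regions()) {
      if (region %in% design$native_regions[[i]]) next
      if (design_pops(design, region)[i] > 0) {
        contrasts[[length(contrasts) + 1L]] <- data.frame(
          species = design$species[i],
          native_region = design$native_primary[i],
          away_region = region,
          growth_form = design$growth_form[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else
    data.frame(species = character(), native_region = character(),
               away_region = character(), growth_form = character())
  list(n_species = nrow(design),
       n_woody = sum(design$growth_form == "woody"),
       n_herbaceous = sum(design$growth_form == "herbaceous"),
       n_invasive = sum(design$is_invasive),
       contrasts = contrasts,
       n_contrasts = nrow(contrasts))
}
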