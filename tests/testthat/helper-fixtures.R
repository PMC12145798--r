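# Fixtures built in code: toy trait tables, a reduced study design, and a
# hand-made standardized trait matrix for direct sampler checks.

trait_defaults <- function() {
  list(cyan = 10, alkaloids = 0.4, fiber = 40, cell_wall = 1, protein = 0.7,
       cn = 20, c_mass = 44, n_mass = 2.3, sla = 300,
       soil_ph = 6, gli = NA_real_, mat = 10, map = 900)
}

# Build a valid trait_table from a minimal row description, filling all
# unspecified traits/covariates with plausible constants.
make_table <- function(df) {
  defs <- trait_defaults()
  for (nm in names(defs)) {
    if (is.null(df[[nm]])) {
      # spread filled-in columns a little so no trait is constant
      df[[nm]] <- defs[[nm]] * seq(0.9, 1.1, length.out = max(nrow(df), 2))[seq_len(nrow(df))]
    }
  }
  if (is.null(df$population_id)) {
    df$population_id <- sprintf("%s_%s_%02d", gsub(" ", "_", df$species),
                                df$region_sampled, seq_len(nrow(df)))
  }
  if (is.null(df$is_home)) df$is_home <- df$region_sampled == df$native_region
  trait_table(df)
}

# n populations of one species in one region, with given values for a trait.
species_rows <- function(species, native, region, growth_form, trait, values) {
  df <- data.frame(species = species, region_sampled = region,
                   native_region = native, growth_form = growth_form,
                   stringsAsFactors = FALSE)[rep(1, length(values)), ]
  df[[trait]] <- values
  rownames(df) <- NULL
  df
}

# The printed-means worked example: a Japanese woody invader whose SLA rises
# from a home mean of 282.4 to 338.1 in the USA, with Japanese woody natives
# averaging 302.4 and US woody natives 354.6 (species means).
worked_example_table <- function() {
  rows <- rbind(
    species_rows("Lonicera japonica", "Japan", "Japan", "woody", "sla",
                 282.4 + c(-20, -5, 5, 20)),
    species_rows("Lonicera japonica", "Japan", "USA", "woody", "sla",
                 338.1 + c(-12, 0, 12)),
    species_rows("Native JP A", "Japan", "Japan", "woody", "sla",
                 300.4 + c(-10, 10)),
    species_rows("Native JP B", "Japan", "Japan", "woody", "sla",
                 304.4 + c(-8, 8)),
    species_rows("Native US A", "USA", "USA", "woody", "sla",
                 350.0 + c(-15, 15)),
    species_rows("Native US B", "USA", "USA", "woody", "sla",
                 359.2 + c(-5, 5)))
  make_table(rows)
}

# A reduced all-woody study design written through the documented CSV
# interface: `per_region` species native to each region, each invasive in
# the next region over, sampled `pops` times at home and away.
mini_design <- function(per_region = 4, pops = 4) {
  regions <- c("France", "Japan", "USA")
  away <- c(France = "Japan", Japan = "USA", USA = "France")
  rows <- list()
  for (r in regions) {
    for (k in seq_len(per_region)) {
      p <- c(France = 0L, Japan = 0L, USA = 0L)
      p[r] <- pops
      p[away[r]] <- pops
      rows[[length(rows) + 1L]] <- data.frame(
        species = sprintf("%s sp%d", r, k), family = "Testaceae",
        growth_form = "woody", native_to = r, invasive_in = away[[r]],
        pops_france = p[["France"]], pops_japan = p[["Japan"]],
        pops_usa = p[["USA"]], stringsAsFactors = FALSE)
    }
  }
  path <- tempfile(fileext = ".csv")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  read_study_design(path)
}

# A standardized trait matrix built directly from z-scale values, for
# sampler checks that need exact control over the data.
make_tm <- function(species, native_region, is_home, y, trait = "sla",
                    growth_form = "woody") {
  n <- length(y)
  data <- data.frame(
    species = species,
    population_id = sprintf("pop%03d", seq_len(n)),
    region_sampled = ifelse(is_home, native_region,
                            ifelse(native_region == "France", "Japan", "France")),
    native_region = native_region,
    growth_form = growth_form,
    is_home = is_home,
    stringsAsFactors = FALSE)
  for (tr in jointhelocals:::jtl_traits()) data[[tr]] <- 0
  data[[trait]] <- y
  transforms <- stats::setNames(lapply(jointhelocals:::jtl_traits(), function(tr) {
    list(log = tr %in% jointhelocals:::logged_traits(), zero_offset = NA_real_,
         center = 0, scale = 1, subset = growth_form)
  }), jointhelocals:::jtl_traits())
  structure(list(data = data, transforms = transforms), class = "trait_matrix")
}
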