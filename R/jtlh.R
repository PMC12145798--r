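# The "join the locals" test: compare each invader's home-away trait shift
# (Y) with the difference in native-community means between the same two
# regions (X). A positive X-Y relationship means invaders shift toward the
# trait values of the native community in the recipient range.

# Transform one trait column per the analysis rule (natural log except cell
# wall; zeros replaced by half the smallest positive value in the column).
transform_trait_values <- function(values, trait) {
  if (!trait %in% logged_traits()) return(values)
  v <- values
  if (any(!is.na(v) & v == 0)) {
    pos <- v[!is.na(v) & v > 0]
    if (!length(pos)) stopf("trait %s has zeros but no positive values", trait)
    v[!is.na(v) & v == 0] <- min(pos) / 2
  }
  log(v)
}

trait_values_on_scale <- function(table, trait, scale) {
  v <- table[[trait]]
  if (scale == "transformed") v <- transform_trait_values(v, trait)
  v
}

#' Invader home-away shift for one trait
#'
#' Mean trait value over the invader's home-range populations minus the
#' mean over its populations in `away_region`; populations are weighted
#' equally. Positive values mean larger trait values at home.
#'
#' @param table A [trait_table()].
#' @param species Focal invader.
#' @param trait Trait name.
#' @param away_region Region of the away populations.
#' @param scale `"raw"` (trait units) or `"transformed"` (log scale, except
#'   cell wall).
#' @return The shift (home mean - away mean).
#' @export
invader_shift <- function(table, species, trait, away_region,
                          scale = c("raw", "transformed")) {
  stopifnot(inherits(table, "trait_table"), trait %in% jtl_traits())
  scale <- match.arg(scale)
  v <- trait_values_on_scale(table, trait, scale)
  sp <- table$species == species
  if (!any(sp)) stopf("species '%s' not in table", species)
  home_v <- v[sp & table$is_home]
  away_v <- v[sp & table$region_sampled == away_region & !table$is_home]
  home_v <- home_v[!is.na(home_v)]
  away_v <- away_v[!is.na(away_v)]
  if (!length(home_v) || !length(away_v)) {
    stopf("undefined contrast for %s in %s: no non-missing %s observations",
          species, if (!length(home_v)) "home range" else away_region, trait)
  }
  mean(home_v) - mean(away_v)
}

#' Native-community regional difference for one trait
#'
#' Mean over native species of the focal invader's home region (same growth
#' form, focal species excluded to avoid circularity) of their species-level
#' trait means, minus the same mean for species native to `away_region`.
#' Only observations from a species' own native region contribute, so
#' away-range populations of other invaders never enter the native means.
#'
#' @inheritParams invader_shift
#' @param weighting `"species"` (default: population means averaged within
#'   species, species weighted equally) or `"population"` (all native
#'   populations pooled).
#' @return The difference (home-region native mean - away-region native mean).
#' @export
native_difference <- function(table, species, trait, away_region,
                              scale = c("raw", "transformed"),
                              weighting = c("species", "population")) {
  stopifnot(inherits(table, "trait_table"), trait %in% jtl_traits())
  scale <- match.arg(scale)
  weighting <- match.arg(weighting)
  sp_rows <- table$species == species
  if (!any(sp_rows)) stopf("species '%s' not in table", species)
  home_region <- unique(table$native_region[sp_rows])[1]
  if (home_region == away_region) stopf("home and away regions must differ")
  gf <- unique(table$growth_form[sp_rows])[1]
  v <- trait_values_on_scale(table, trait, scale)

  region_native_mean <- function(region, exclude) {
    keep <- table$native_region == region &
      table$region_sampled == region &
      table$growth_form == gf &
      !(table$species %in% exclude) &
      !is.na(v)
    if (!any(keep)) {
      stopf("no qualifying %s native species with %s data in %s",
            gf, trait, region)
    }
    if (weighting == "population") return(mean(v[keep]))
    mean(tapply(v[keep], table$species[keep], mean))
  }
  region_native_mean(home_region, exclude = species) -
    region_native_mean(away_region, exclude = species)
}

#' Build the contrast table for one trait
#'
#' One row per eligible (invader, away region) pair, pairing the invader's
#' home-away shift with the native-community regional difference. The
#' eligible pairs come from the study design when one is available (either
#' passed explicitly or attached to the table by [generate_traits()]);
#' otherwise every species with both home and away observations is treated
#' as an invader in each away region where it was sampled. Pairs whose
#' shift or native difference is undefined (no non-missing data on one
#' side) are dropped, with the reason recorded in the `"dropped"` attribute.
#'
#' @inheritParams native_difference
#' @param design Optional `study_design` supplying the invasive flags.
#' @return A `contrast_table` data.frame with columns `species`,
#'   `native_region`, `away_region`, `growth_form`, `trait`,
#'   `invader_shift`, `native_difference`, `scale`.
#' @export
build_contrast_table <- function(table, trait,
                                 scale = c("transformed", "raw"),
                                 weighting = c("species", "population"),
                                 design = NULL) {
  stopifnot(inherits(table, "trait_table"), trait %in% jtl_traits())
  scale <- match.arg(scale)
  weighting <- match.arg(weighting)
  if (is.null(design)) design <- attr(table, "design")
  if (!is.null(design)) {
    pairs <- design_summary(design)$contrasts
    pairs <- pairs[pairs$species %in% table$species, , drop = FALSE]
  } else {
    pairs <- unique(table[!table$is_home,
                          c("species", "native_region", "growth_form",
                            "region_sampled")])
    names(pairs)[names(pairs) == "region_sampled"] <- "away_region"
    has_home <- vapply(pairs$species,
                       function(s) any(table$species == s & table$is_home),
                       TRUE)
    pairs <- pairs[has_home, , drop = FALSE]
  }
  rows <- list()
  dropped <- list()
  for (i in seq_len(nrow(pairs))) {
    res <- tryCatch({
      shift <- invader_shift(table, pairs$species[i], trait,
                             pairs$away_region[i], scale = scale)
      nd <- native_difference(table, pairs$species[i], trait,
                              pairs$away_region[i], scale = scale,
                              weighting = weighting)
      data.frame(species = pairs$species[i],
                 native_region = pairs$native_region[i],
                 away_region = pairs$away_region[i],
                 growth_form = pairs$growth_form[i],
                 trait = trait,
                 invader_shift = shift,
                 native_difference = nd,
                 scale = scale,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        species = pairs$species[i], away_region = pairs$away_region[i],
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), native_region = character(),
               away_region = character(), growth_form = character(),
               trait = character(), invader_shift = numeric(),
               native_difference = numeric(), scale = character())
  rownames(out) <- NULL
  class(out) <- unique(c("contrast_table", class(out)))
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  out
}

#' Ordinary least-squares slope, intercept and R-squared
#'
#' Closed-form simple linear regression of `y` on `x`; R-squared is the
#' squared Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length (>= 2 points, `var(x) > 0`).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
ols_slope <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stopf("need at least 2 points")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stopf("x is constant: slope undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy == 0) 0 else stats::cor(x, y)^2
  list(slope = slope, intercept = intercept, r_squared = r2, n = n)
}

#' Bootstrap test for a positive shift-vs-difference slope
#'
#' Because contrasts share native species across regions, the observed OLS
#' slope of invader shift on native regional difference is tested against a
#' null distribution built by breaking the X-Y pairing: X and Y are each
#' resampled with replacement, independently, `B` times (a within-margin
#' permutation of Y is available as a sensitivity option). The one-sided
#' p-value for a positive slope is `(1 + #{null slope >= observed}) /
#' (B + 1)`.
#'
#' @param contrasts A `contrast_table` (>= 3 rows, non-constant X).
#' @param B Number of null resamples (default 1000).
#' @param seed Integer seed; fixed seed reproduces the null distribution.
#' @param method `"bootstrap"` (independent resampling of both margins,
#'   default) or `"permutation"` (Y shuffled against fixed X).
#' @return A `jtlh_result`: trait, number of contrasts, observed slope,
#'   intercept and R-squared, the `B` null slopes, and the p-value.
#' @export
bootstrap_slope_test <- function(contrasts, B = 1000L, seed = 1L,
                                 method = c("bootstrap", "permutation")) {
  stopifnot(inherits(contrasts, "contrast_table"))
  method <- match.arg(method)
  if (B < 1) stopf("B must be at least 1")
  x <- contrasts$native_difference
  y <- contrasts$invader_shift
  n <- nrow(contrasts)
  if (n < 3) stopf("need at least 3 contrasts, got %d", n)
  obs <- ols_slope(x, y)
  set.seed(seed)
  col_slopes <- function(xm, ym) {
    xc <- sweep(xm, 2, colMeans(xm))
    yc <- sweep(ym, 2, colMeans(ym))
    colSums(xc * yc) / colSums(xc^2)
  }
  draw_null <- function(b) {
    if (method == "bootstrap") {
      xm <- matrix(sample(x, n * b, replace = TRUE), n, b)
      ym <- matrix(sample(y, n * b, replace = TRUE), n, b)
    } else {
      xm <- matrix(rep(x, b), n, b)
      ym <- vapply(seq_len(b), function(i) y[sample.int(n)], numeric(n))
    }
    col_slopes(xm, ym)
  }
  null_slopes <- draw_null(B)
  # resampled X can be degenerate (all equal) for small n; redraw those
  for (i in 1:100) {
    bad <- !is.finite(null_slopes)
    if (!any(bad)) break
    null_slopes[bad] <- draw_null(sum(bad))
  }
  null_slopes[!is.finite(null_slopes)] <- 0
  p <- (1 + sum(null_slopes >= obs$slope)) / (B + 1)
  structure(list(trait = contrasts$trait[1] %||% NA_character_,
                 n_contrasts = n, slope = obs$slope,
                 intercept = obs$intercept, r_squared = obs$r_squared,
                 B = as.integer(B), null_slopes = null_slopes,
                 p_value = p, method = method, seed = as.integer(seed)),
            class = "jtlh_result")
}

#' @export
print.jtlh_result <- function(x, ...) {
  cat(sprintf(
    "Join-the-locals test (%s): n = %d, slope = %.3f, R2 = %.3f, p = %.4g\n",
    x$trait, x$n_contrasts, x$slope, x$r_squared, x$p_value))
  invisible(x)
}
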