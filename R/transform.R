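#' Log-transform the nine traits of a trait table
#'
#' Natural log is applied to every trait except cell wall mass, which stays
#' on the raw scale (logging it increases rather than decreases skew).
#' Exact zeros (valid only for the assay-floor traits) are replaced by half
#' the smallest positive observed value of that trait before logging, the
#' standard detection-floor convention. Missing cells stay missing. The
#' transform record per trait suffices to invert the transformation exactly.
#'
#' @param table A [trait_table()].
#' @return A `trait_matrix`: a list with `data` (meta columns plus the nine
#'   transformed trait columns) and `transforms` (per-trait records with
#'   `log`, `zero_offset`, `center`, `scale`, `subset`).
#' @export
log_transform <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  meta_cols <- c("species", "population_id", "region_sampled",
                 "native_region", "growth_form", "is_home")
  data <- table[, c(meta_cols, jtl_traits())]
  data <- as.data.frame(data)
  transforms <- list()
  for (tr in jtl_traits()) {
    v <- data[[tr]]
    if (any(!is.na(v) & v < 0)) stopf("negative values in trait %s", tr)
    use_log <- tr %in% logged_traits()
    zero_offset <- NA_real_
    if (use_log) {
      if (any(!is.na(v) & v == 0)) {
        pos <- v[!is.na(v) & v > 0]
        if (!length(pos)) stopf("trait %s has zeros but no positive values", tr)
        zero_offset <- min(pos) / 2
        v[!is.na(v) & v == 0] <- zero_offset
      }
      v <- log(v)
    }
    data[[tr]] <- v
    transforms[[tr]] <- list(log = use_log, zero_offset = zero_offset,
                             center = NA_real_, scale = NA_real_,
                             subset = "all")
  }
  structure(list(data = data, transforms = transforms),
            class = "trait_matrix")
}

#' Z-standardize transformed traits within a subset
#'
#' Standardizes each trait to mean 0, SD 1 over its non-missing values
#' within the chosen growth-form subset (the univariate models analyze
#' woody and herbaceous species separately; `"all"` pools both, as used for
#' the cross-region descriptive tables). The returned matrix contains only
#' the subset rows, and the per-trait `(center, scale)` is recorded so the
#' transformation can be inverted.
#'
#' @param tm A `trait_matrix` from [log_transform()].
#' @param subset `"all"`, `"woody"` or `"herbaceous"`.
#' @return A standardized `trait_matrix` restricted to the subset rows.
#' @export
z_standardize <- function(tm, subset = c("all", "woody", "herbaceous")) {
  stopifnot(inherits(tm, "trait_matrix"))
  subset <- match.arg(subset)
  data <- tm$data
  if (subset != "all") data <- data[data$growth_form == subset, , drop = FALSE]
  if (nrow(data) == 0) stopf("no observations in subset '%s'", subset)
  transforms <- tm$transforms
  for (tr in jtl_traits()) {
    v <- data[[tr]]
    ok <- !is.na(v)
    if (sum(ok) < 2) {
      stopf("trait %s has fewer than 2 non-missing values in subset '%s'",
            tr, subset)
    }
    m <- mean(v[ok])
    s <- stats::sd(v[ok])
    if (s == 0) stopf("trait %s has zero variance in subset '%s' (degenerate)",
                      tr, subset)
    data[[tr]] <- (v - m) / s
    transforms[[tr]]$center <- m
    transforms[[tr]]$scale <- s
    transforms[[tr]]$subset <- subset
  }
  rownames(data) <- NULL
  structure(list(data = data, transforms = transforms),
            class = "trait_matrix")
}

#' Invert the transformation for one trait
#'
#' Maps standardized values back to raw trait units using the stored
#' transform record: unstandardize with the recorded (center, scale), then
#' exponentiate if the trait was logged. Offset-adjusted zeros come back as
#' the offset value (half the smallest positive observation), not zero.
#'
#' @param tm A standardized `trait_matrix`.
#' @param trait Trait name.
#' @param z Numeric vector of standardized values (defaults to the trait's
#'   column in `tm`).
#' @return Numeric vector on the raw scale.
#' @export
invert_transform <- function(tm, trait, z = NULL) {
  stopifnot(inherits(tm, "trait_matrix"), trait %in% jtl_traits())
  rec <- tm$transforms[[trait]]
  if (is.null(z)) z <- tm$data[[trait]]
  v <- z
  if (!is.na(rec$center)) v <- v * rec$scale + rec$center
  if (rec$log) v <- exp(v)
  v
}

#' @export
print.trait_matrix <- function(x, ...) {
  std <- vapply(x$transforms, function(r) !is.na(r$center), TRUE)
  cat(sprintf("trait_matrix: %d observations, %d traits (%s)\n",
              nrow(x$data), length(jtl_traits()),
              if (all(std)) sprintf("standardized within '%s'",
                                    x$transforms[[1]]$subset)
              else "log scale, not standardized"))
  invisible(x)
}
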