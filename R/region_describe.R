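# Descriptive/frequentist comparisons across regions and growth forms:
# one-way ANOVA with Tukey HSD letters, and Welch t tests.

#' One-way ANOVA of a variable across regions, with Tukey HSD letters
#'
#' Classical one-way ANOVA with region as the predictor, followed by Tukey
#' honestly-significant-difference comparisons on all region pairs
#' (Tukey-Kramer adjustment for unequal group sizes, via
#' `stats::TukeyHSD`), and a compact letter display at alpha = 0.05.
#' Traits are analyzed on the log scale by default (cell wall mass and the
#' environment covariates untransformed), while the reported group means
#' and standard errors stay on the raw scale, as in field-study summary
#' tables. Regions with fewer than 2 observations are dropped with a
#' warning.
#'
#' @param table A [trait_table()].
#' @param variable A trait or environment covariate column name.
#' @param transform `NULL` (default rule above), `TRUE` (log), or `FALSE`.
#' @return An `anova_result`: per-region `means` (raw-scale mean, SE, n,
#'   letter), `f`, `df` (numerator, denominator), `p_value`, the Tukey
#'   pairwise p-value matrix, and the transform actually used.
#' @export
region_anova <- function(table, variable, transform = NULL) {
  stopifnot(inherits(table, "trait_table"))
  if (!variable %in% c(jtl_traits(), jtl_env_vars())) {
    stopf("unknown variable '%s'", variable)
  }
  if (is.null(transform)) {
    transform <- variable %in% logged_traits()
  }
  raw <- table[[variable]]
  region <- table$region_sampled
  ok <- !is.na(raw)
  raw <- raw[ok]; region <- region[ok]
  counts <- vapply(split(raw, region), length, 0L)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warnf("dropping region(s) with fewer than 2 observations: %s",
          paste(small, collapse = ", "))
    keep <- !region %in% small
    raw <- raw[keep]; region <- region[keep]
  }
  if (length(unique(region)) < 2) {
    stopf("need at least 2 regions with >= 2 observations")
  }
  v <- if (transform) transform_trait_values(raw, variable) else raw
  region <- factor(region)
  fit <- stats::aov(v ~ region)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$region
  regions <- levels(region)
  k <- length(regions)
  pmat <- matrix(1, k, k, dimnames = list(regions, regions))
  for (row in rownames(tk)) {
    pair <- strsplit(row, "-", fixed = TRUE)[[1]]
    pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tk[row, "p adj"]
  }
  letters_out <- compact_letters(pmat)
  means <- data.frame(
    region = regions,
    mean = as.numeric(tapply(raw, region, mean)),
    se = as.numeric(tapply(raw, region, function(z) stats::sd(z) / sqrt(length(z)))),
    n = as.integer(vapply(split(raw, region), length, 0L)),
    letters = letters_out[regions])
  rownames(means) <- NULL
  structure(list(variable = variable, transform = transform, means = means,
                 f = an[1, "F value"],
                 df = c(an[1, "Df"], an[2, "Df"]),
                 p_value = an[1, "Pr(>F)"],
                 tukey_p = pmat),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s across regions%s\n", x$variable,
              if (x$transform) " (log scale)" else ""))
  for (i in seq_len(nrow(x$means))) {
    cat(sprintf("  %-8s %.3g +/- %.2g %s (n=%d)\n", x$means$region[i],
                x$means$mean[i], x$means$se[i], x$means$letters[i],
                x$means$n[i]))
  }
  cat(sprintf("  F = %.4g on %d, %d df; p = %.3g\n",
              x$f, x$df[1], x$df[2], x$p_value))
  invisible(x)
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom (which are
#' typically fractional), two-sided.
#'
#' @param a,b Numeric vectors (>= 2 non-missing values each).
#' @return A `ttest_result`: group means, `t`, `df`, `p_value`.
#' @export
welch_ttest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stopf("each group needs at least 2 non-missing values")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Welch t test: means %.4g vs %.4g, t = %.4g on %.3f df, p = %.3g\n",
              x$mean_a, x$mean_b, x$t, x$df, x$p_value))
  invisible(x)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' The insert-and-absorb algorithm: start from one set containing all
#' groups; for each significantly different pair, split every set that
#' contains both members; finally absorb sets that are subsets of others.
#' Two groups share a letter if and only if they are not significantly
#' different at `alpha`.
#'
#' @param p_matrix Symmetric matrix of pairwise p-values with group names
#'   as dimnames.
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letters <- function(p_matrix, alpha = 0.05) {
  p_matrix <- as.matrix(p_matrix)
  if (nrow(p_matrix) != ncol(p_matrix) ||
      !isTRUE(all.equal(p_matrix, t(p_matrix), tolerance = 1e-12))) {
    stopf("p-value matrix must be symmetric")
  }
  groups <- rownames(p_matrix) %||% as.character(seq_len(nrow(p_matrix)))
  sets <- list(groups)
  k <- nrow(p_matrix)
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (p_matrix[i, j] >= alpha) next
      gi <- groups[i]; gj <- groups[j]
      new_sets <- list()
      for (s in sets) {
        if (gi %in% s && gj %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, gi)), list(setdiff(s, gj)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb: drop sets contained in another set
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[b] &&
              all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  # order letter sets by their first group for a stable display
  first <- vapply(sets, function(s) min(match(s, groups)), 0L)
  sets <- sets[order(first)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (idx in seq_along(sets)) {
    for (g in sets[[idx]]) out[g] <- paste0(out[g], letters[idx])
  }
  out
}
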