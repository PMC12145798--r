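test_that("the printed-means worked example reproduces shift and native difference", {
  tab <- worked_example_table()
  shift <- invader_shift(tab, "Lonicera japonica", "sla", "USA", scale = "raw")
  expect_equal(shift, 282.4 - 338.1, tolerance = 1e-9)
  nd <- native_difference(tab, "Lonicera japonica", "sla", "USA", scale = "raw")
  expect_equal(nd, 302.4 - 354.6, tolerance = 1e-9)
  # consistent with a near-1:1 point: same sign, similar magnitude
  expect_identical(sign(shift), sign(nd))
  expect_lt(abs(shift - nd), 10)
})

test_that("invader shift handles degenerate and missing cases", {
  tab <- worked_example_table()
  same <- make_table(rbind(
    species_rows("Inv", "Japan", "Japan", "woody", "sla", c(300, 310)),
    species_rows("Inv", "Japan", "USA", "woody", "sla", c(300, 310))))
  expect_equal(invader_shift(same, "Inv", "sla", "USA", scale = "raw"), 0)
  gone <- as.data.frame(tab)
  gone$sla[gone$species == "Lonicera japonica" &
             gone$region_sampled == "USA"] <- NA
  gone <- trait_table(gone)
  expect_error(invader_shift(gone, "Lonicera japonica", "sla", "USA"),
               "undefined contrast")
})

test_that("native means exclude the focal species and non-native populations", {
  # four-species toy: direct enumeration oracle
  tab <- make_table(rbind(
    species_rows("Focal", "Japan", "Japan", "woody", "sla", c(280, 290)),
    species_rows("Focal", "Japan", "USA", "woody", "sla", c(330, 340)),
    species_rows("JP nat", "Japan", "Japan", "woody", "sla", c(300, 320)),
    species_rows("US nat A", "USA", "USA", "woody", "sla", c(350, 370)),
    species_rows("US nat B", "USA", "USA", "woody", "sla", c(390, 410)),
    # an away-range population of another invader in the USA: never counted
    species_rows("FR inv", "France", "USA", "woody", "sla", c(9000, 9000)),
    # and a herbaceous native: wrong growth form, never counted
    species_rows("US herb", "USA", "USA", "herbaceous", "sla", c(50, 60))))
  nd <- native_difference(tab, "Focal", "sla", "USA", scale = "raw")
  expect_equal(nd, 310 - mean(c(360, 400)), tolerance = 1e-12)
  # artificially including the focal in the home pool changes the value
  with_focal <- mean(c(310, 285)) - mean(c(360, 400))
  expect_false(isTRUE(all.equal(nd, with_focal)))
  # population weighting pools rather than averages species means
  nd_pop <- native_difference(tab, "Focal", "sla", "USA", scale = "raw",
                              weighting = "population")
  expect_equal(nd_pop, 310 - mean(c(350, 370, 390, 410)), tolerance = 1e-12)
  expect_error(native_difference(tab, "Focal", "sla", "France"),
               "no qualifying")
})

test_that("contrast tables enumerate design pairs and log dropped rows", {
  gen <- generate_traits(synthetic_config(
    region_offsets = jointhelocals:::jtl_default_offsets(),
    missing_rate = 0, scenario = "join_the_locals", seed = 12))
  ct <- build_contrast_table(gen$table, "sla")
  expect_identical(nrow(ct), 33L)
  expect_null(attr(ct, "dropped"))
  # single-invader toy matches hand computation
  toy <- make_table(rbind(
    species_rows("Inv", "Japan", "Japan", "woody", "sla", c(280, 300)),
    species_rows("Inv", "Japan", "USA", "woody", "sla", c(330, 350)),
    species_rows("JP nat", "Japan", "Japan", "woody", "sla", c(300, 310)),
    species_rows("US nat", "USA", "USA", "woody", "sla", c(360, 380))))
  ct1 <- build_contrast_table(toy, "sla", scale = "raw")
  expect_identical(nrow(ct1), 1L)
  expect_equal(ct1$invader_shift, 290 - 340, tolerance = 1e-12)
  expect_equal(ct1$native_difference, 305 - 370, tolerance = 1e-12)
  # an invader with all away data missing is dropped with a reason
  toy2 <- as.data.frame(toy)
  toy2$sla[toy2$species == "Inv" & toy2$region_sampled == "USA"] <- NA
  ct2 <- build_contrast_table(trait_table(toy2), "sla", scale = "raw")
  expect_identical(nrow(ct2), 0L)
  expect_match(attr(ct2, "dropped")$reason, "undefined contrast")
})

test_that("ols_slope matches the normal equations and handles edge cases", {
  expect_equal(ols_slope(c(0, 1), c(0, 2)),
               list(slope = 2, intercept = 0, r_squared = 1, n = 2L),
               tolerance = 1e-12)
  set.seed(4)
  x <- rnorm(40); y <- 1.5 * x + rnorm(40)
  fit <- ols_slope(x, y)
  co <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
  expect_equal(fit$slope, co[2], tolerance = 1e-12)
  expect_equal(fit$intercept, co[1], tolerance = 1e-12)
  set.seed(5)
  big <- ols_slope(rnorm(1000), rnorm(1000))
  expect_lt(big$r_squared, 0.01)
  expect_error(ols_slope(rep(1, 5), rnorm(5)), "constant")
})

test_that("bootstrap slope test detects strong signal and respects the plus-one rule", {
  x <- seq(-1, 1, length.out = 33)
  ct <- structure(data.frame(species = paste0("s", 1:33),
                             native_region = "Japan", away_region = "USA",
                             growth_form = "woody", trait = "sla",
                             invader_shift = x, native_difference = x,
                             scale = "raw"),
                  class = c("contrast_table", "data.frame"))
  res <- bootstrap_slope_test(ct, B = 1000, seed = 2)
  expect_equal(res$slope, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)
  expect_identical(length(res$null_slopes), 1000L)
  # constant Y: slope 0 and p = 1 under the plus-one rule
  ct$invader_shift <- rep(2, 33)
  flat <- bootstrap_slope_test(ct, B = 500, seed = 3)
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)
})

test_that("bootstrap null is deterministic under a fixed seed and B", {
  gen <- generate_traits(scenario_presets("join_the_locals", seed = 31))
  ct <- build_contrast_table(gen$table, "n_mass")
  a <- bootstrap_slope_test(ct, B = 400, seed = 17)
  b <- bootstrap_slope_test(ct, B = 400, seed = 17)
  expect_identical(a$null_slopes, b$null_slopes)
  expect_identical(a$p_value, b$p_value)
  d <- bootstrap_slope_test(ct, B = 400, seed = 18)
  expect_false(identical(a$null_slopes, d$null_slopes))
  # permutation variant is available and also deterministic
  p1 <- bootstrap_slope_test(ct, B = 400, seed = 17, method = "permutation")
  p2 <- bootstrap_slope_test(ct, B = 400, seed = 17, method = "permutation")
  expect_identical(p1$null_slopes, p2$null_slopes)
})

test_that("shifts are scale-equivariant and the bootstrap p is scale-invariant", {
  gen <- generate_traits(synthetic_config(
    region_offsets = jointhelocals:::jtl_default_offsets(),
    missing_rate = 0, seed = 61))
  tab <- gen$table
  scaled <- as.data.frame(tab)
  scaled$sla <- scaled$sla * 3
  scaled <- trait_table(scaled)
  attr(scaled, "design") <- attr(tab, "design")
  sp <- "Lonicera japonica"
  s1 <- invader_shift(tab, sp, "sla", "USA", scale = "raw")
  s2 <- invader_shift(scaled, sp, "sla", "USA", scale = "raw")
  expect_equal(s2, 3 * s1, tolerance = 1e-12)
  n1 <- native_difference(tab, sp, "sla", "USA", scale = "raw")
  n2 <- native_difference(scaled, sp, "sla", "USA", scale = "raw")
  expect_equal(n2, 3 * n1, tolerance = 1e-12)
  ct1 <- build_contrast_table(tab, "sla", scale = "raw")
  ct2 <- build_contrast_table(scaled, "sla", scale = "raw")
  b1 <- bootstrap_slope_test(ct1, B = 500, seed = 7)
  b2 <- bootstrap_slope_test(ct2, B = 500, seed = 7)
  expect_equal(b1$slope, b2$slope, tolerance = 1e-12)
  expect_identical(b1$p_value, b2$p_value)
})
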