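# plateau estimation and steady-state dilution equations

test_that("a constant window is a steady plateau with zero cv", {
  out <- estimate_plateau(
    tibble::tibble(timepoint_min = c(160, 170, 180),
                   enrichment = rep(0.05, 3)), c(160, 180))
  expect_equal(out$mean_enrichment, 0.05)
  expect_equal(out$cv, 0)
  expect_equal(out$slope_per_min, 0)
  expect_true(out$steady)
  expect_equal(out$n_points, 3L)
})

test_that("a rising window reports the hand-computed slope and fails QC", {
  out <- estimate_plateau(
    tibble::tibble(timepoint_min = c(160, 170, 180),
                   enrichment = c(0.04, 0.05, 0.06)), c(160, 180))
  # slope of a perfect line through the three points
  expect_equal(out$slope_per_min, 0.001, tolerance = 1e-12)
  expect_equal(out$mean_enrichment, 0.05)
  expect_equal(out$cv, 0.01 / 0.05, tolerance = 1e-9)
  # cv = 0.2 > 0.1 and the drift is real: not steady
  expect_false(out$steady)
})

test_that("plateau estimation needs at least two points in the window", {
  expect_error(estimate_plateau(
    tibble::tibble(timepoint_min = 170, enrichment = 0.05), c(160, 180)),
    ">= 2 points")
})

test_that("plateau estimation is grouped by the extra columns", {
  d <- tidyr::crossing(animal_id = c("a", "b"),
                       timepoint_min = c(160, 170, 180)) |>
    dplyr::mutate(enrichment = ifelse(animal_id == "a", 0.05, 0.08))
  out <- estimate_plateau(d, c(160, 180))
  expect_equal(nrow(out), 2)
  expect_equal(out$mean_enrichment[out$animal_id == "b"], 0.08)
})

test_that("dilution Ra matches hand arithmetic in both conventions", {
  expect_equal(ra_steady_state(2.5, 1), 2.5)               # pure tracer
  expect_equal(ra_steady_state(2.5, 0.05), 50)
  expect_equal(ra_steady_state(2.5, 0.05, "tracer_corrected"), 47.5)
  expect_error(ra_steady_state(2.5, 0), "positive")
  expect_error(ra_steady_state(0, 0.05), "positive")
})

test_that("simplified minus tracer-corrected Ra equals F exactly", {
  set.seed(5)
  f <- runif(20, 0.1, 5)
  e <- runif(20, 0.01, 0.99)
  expect_equal(ra_steady_state(f, e) -
                 ra_steady_state(f, e, "tracer_corrected"), f,
               tolerance = 1e-12)
  # and Ra is strictly decreasing in plateau enrichment
  es <- sort(e)
  expect_true(all(diff(ra_steady_state(1, es)) < 0))
})

test_that("RaCO2 is bicarbonate rate over breath plateau enrichment", {
  expect_equal(ra_co2(0.15, 0.01), 15)
  expect_equal(ra_co2(0.15, 1), 0.15)
  expect_error(ra_co2(0.15, 0), "positive")
})

test_that("palmitate oxidation follows the bicarbonate-anchored equation", {
  expect_equal(palmitate_oxidation(1500, 0.0008, 0.05), 1.5)
  expect_equal(palmitate_oxidation(1500, 0, 0.05), 0)
  # algebraic cancellation: RaCO2 = n and equal enrichments give 1
  expect_equal(palmitate_oxidation(16, 0.05, 0.05), 1)
  expect_error(palmitate_oxidation(1500, 0.0008, 0), "positive")
  # rates scale linearly with F through RaCO2
  expect_equal(palmitate_oxidation(3000, 0.0008, 0.05),
               2 * palmitate_oxidation(1500, 0.0008, 0.05))
})

test_that("fraction oxidized is Rox/Rd with a warning above 1", {
  expect_equal(fraction_oxidized(0, 6), 0)
  expect_equal(fraction_oxidized(6, 6), 1)
  expect_equal(fraction_oxidized(1.5, 6), 0.25)
  expect_warning(out <- fraction_oxidized(7, 6), "exceeds 1")
  expect_equal(out, 7 / 6)
  expect_error(fraction_oxidized(1, 0), "positive")
})

test_that("fractional TCA contribution is the enrichment quotient", {
  expect_equal(fractional_tca_contribution(0, 0.1), 0)
  expect_equal(fractional_tca_contribution(0.02, 0.10), 0.2)
  expect_error(fractional_tca_contribution(0.02, 0), "positive")
  # linear in the citrate enrichment at fixed denominator
  x <- seq(0, 0.05, by = 0.01)
  expect_equal(fractional_tca_contribution(x, 0.1), x / 0.1)
})
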