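# study orchestration, QC behaviour, tidiers and plots

test_that("duplicate animal rows are a validation error", {
  sim <- simulate_flux_study(zero_noise_truth(n_animals = 2))
  dup <- dplyr::bind_rows(sim$animals, sim$animals[1, ])
  expect_error(run_flux_study(sim$gcms, sim$breath, dup), "duplicated")
})

test_that("an empty animal set yields an empty report with a warning", {
  sim <- simulate_flux_study(zero_noise_truth(n_animals = 2))
  expect_warning(
    fit <- run_flux_study(sim$gcms, sim$breath, sim$animals[0, ]),
    "empty animal set")
  expect_s3_class(fit, "flux_study")
  expect_equal(nrow(fit$animals), 0)
})

test_that("missing plateau timepoints flag the animal, study continues", {
  sim <- simulate_flux_study(zero_noise_truth(n_animals = 3))
  # leave animal m02 a single sample in the plasma plateau window
  gcms <- sim$gcms[!(sim$gcms$animal_id == "m02" &
                       sim$gcms$timepoint_min > 160), ]
  fit <- run_flux_study(gcms, sim$breath, sim$animals)
  expect_true(any(grepl("m02", fit$qc)))
  bad <- fit$animals[fit$animals$animal_id == "m02", ]
  ok <- fit$animals[fit$animals$animal_id != "m02", ]
  expect_true(is.na(bad$ra_glycerol))
  expect_true(all(is.finite(ok$ra_glycerol)))
  expect_match(bad$qc_flags, "plateau_missing")
})

test_that("a missing breath baseline flags only the breath chain", {
  sim <- simulate_flux_study(zero_noise_truth(n_animals = 2))
  breath <- sim$breath[!(sim$breath$animal_id == "m01" &
                           sim$breath$timepoint_min == 0), ]
  fit <- run_flux_study(sim$gcms, breath, sim$animals)
  r <- fit$animals[fit$animals$animal_id == "m01", ]
  expect_true(is.na(r$ra_co2))
  expect_false(is.na(r$ra_glycerol))
})

test_that("steady-state identity rd = ra holds in every result row", {
  sim <- simulate_flux_study(simulation_truth(n_animals = 4, seed = 3))
  fit <- run_flux_study(sim$gcms, sim$breath, sim$animals)
  expect_identical(fit$animals$ra_glycerol, fit$animals$rd_glycerol)
  expect_identical(fit$animals$ra_palmitate, fit$animals$rd_palmitate)
})

test_that("two-group summaries carry Welch p-values and group means", {
  truth <- simulation_truth(n_animals = 3, groups = c("ctl", "trt"),
                            group_effect = c(trt = 0.6), seed = 12)
  sim <- simulate_flux_study(truth)
  fit <- run_flux_study(sim$gcms, sim$breath, sim$animals, sim$tissue)
  expect_true("p_welch" %in% names(fit$summary))
  s <- fit$summary[fit$summary$quantity == "ra_glycerol", ]
  expect_equal(nrow(s), 2)
  expect_lt(s$mean[s$group == "trt"], s$mean[s$group == "ctl"])
})

test_that("tidy, glance and autoplot expose the fitted study", {
  sim <- simulate_flux_study(zero_noise_truth(n_animals = 2))
  fit <- run_flux_study(sim$gcms, sim$breath, sim$animals, sim$tissue)
  td <- tidy(fit)
  expect_true(all(c("animal_id", "group", "quantity", "value", "unit",
                    "qc_flags") %in% names(td)))
  expect_true(any(grepl("tca_fraction_", td$quantity)))
  gl <- glance(fit)
  expect_equal(gl$n_animals, 2L)
  expect_equal(gl$n_tissues, 4L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  expect_silent(ggplot2::ggplot_build(p))
  p2 <- plot_enrichment_series(
    tibble::tibble(animal_id = "a", analyte = "glycerol",
                   timepoint_min = c(160, 170, 180),
                   enrichment = c(0.07, 0.071, 0.069)))
  expect_s3_class(p2, "ggplot")
})

test_that("washout correction subtracts the extrapolated bicarbonate tail", {
  sim <- simulate_flux_study(zero_noise_truth(n_animals = 2))
  cfg0 <- flux_config()
  cfg1 <- flux_config(washout_rate_per_min = 0.05)
  fit0 <- run_flux_study(sim$gcms, sim$breath, sim$animals, config = cfg0)
  fit1 <- run_flux_study(sim$gcms, sim$breath, sim$animals, config = cfg1)
  # with the packaged pool sizes the true residual at 140-150 min is
  # negligible, so the correction can only lower the oxidation estimate,
  # and only slightly
  expect_true(all(fit1$animals$palmitate_oxidation <=
                    fit0$animals$palmitate_oxidation + 1e-12))
  expect_equal(fit1$animals$palmitate_oxidation,
               fit0$animals$palmitate_oxidation, tolerance = 0.05)
})
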