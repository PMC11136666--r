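# synthetic-study generator: one-pool dynamics and parameter recovery

test_that("a perfect prime yields a flat enrichment series", {
  pr <- default_protocols()[default_protocols()$analyte == "glycerol", ]
  ra <- 30; q <- 80
  e_ss <- pr$rate_nmol_per_g_min / (ra + pr$rate_nmol_per_g_min)
  pr$prime_nmol_per_g <- q * e_ss
  s <- simulate_enrichment_series(pr, ra, q, times = c(70, 100, 150, 180))
  expect_equal(s$enrichment, rep(e_ss, 4), tolerance = 1e-12)
})

test_that("enrichment approaches F/Ra_total many time constants in", {
  pr <- default_protocols()[default_protocols()$analyte == "palmitate", ]
  ra <- 15; q <- 60
  s <- simulate_enrichment_series(pr, ra, q, times = c(160, 170, 180))
  e_ss <- pr$rate_nmol_per_g_min / (ra + pr$rate_nmol_per_g_min)
  expect_equal(s$enrichment, rep(e_ss, 3), tolerance = 1e-6)
  expect_error(simulate_enrichment_series(pr, ra, q, times = -5),
               "negative")
})

test_that("seeded generators are reproducible", {
  pr <- default_protocols()[default_protocols()$analyte == "glycerol", ]
  a <- simulate_enrichment_series(pr, 30, 80, c(160, 170, 180),
                                  noise_cv = 0.05, seed = 99)
  b <- simulate_enrichment_series(pr, 30, 80, c(160, 170, 180),
                                  noise_cv = 0.05, seed = 99)
  expect_identical(a, b)
  expect_identical(simulate_clams(n_per_group = 2, days = 1, seed = 5),
                   simulate_clams(n_per_group = 2, days = 1, seed = 5))
  s1 <- simulate_flux_study(simulation_truth(n_animals = 2, seed = 8))
  s2 <- simulate_flux_study(simulation_truth(n_animals = 2, seed = 8))
  expect_identical(s1$gcms, s2$gcms)
  expect_identical(s1$breath, s2$breath)
})

test_that("GC-MS synthesis round-trips through correction at zero noise", {
  frag <- default_fragment_panel()$citrate
  cm <- na_correction_matrix(frag)
  set.seed(21)
  x <- random_mid(7)
  raw <- simulate_gcms_intensities(x, frag)
  expect_lt(max(abs(correct_mid(raw$intensity, cm)$fractions - x)), 1e-8)
  # unlabelled truth gives intensities proportional to natural abundance
  raw0 <- simulate_gcms_intensities(c(1, rep(0, 6)), frag)
  expect_equal(raw0$intensity / sum(raw0$intensity),
               cm[, 1] / sum(cm[, 1]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("noisy GC-MS correction is unbiased for interior MIDs", {
  # unbiasedness holds when every isotopomer is truly present; MIDs with
  # structural zeros sit on the non-negativity boundary, where clipped
  # noise inflates the zero channels and renormalization depresses the
  # others by O(cv) -- an inherent property of NNLS correction, checked
  # below as a documented limitation
  frag <- default_fragment_panel()$citrate
  cm <- na_correction_matrix(frag)
  x <- c(0.80, 0.02, 0.06, 0.02, 0.05, 0.02, 0.03)
  set.seed(123)
  m0 <- replicate(400, {
    raw <- simulate_gcms_intensities(x, frag, noise_cv = 0.05)
    correct_mid(raw$intensity, cm)$fractions[1]
  })
  expect_lt(abs(mean(m0) - x[1]), 3 * sd(m0) / sqrt(length(m0)))
  xb <- c(0.9, 0, 0.04, 0, 0.04, 0, 0.02)
  m0b <- replicate(200, {
    raw <- simulate_gcms_intensities(xb, frag, noise_cv = 0.05)
    correct_mid(raw$intensity, cm)$fractions[1]
  })
  # boundary case: small negative M+0 bias from clipping, bounded
  expect_lt(mean(m0b) - xb[1], 0)
  expect_lt(abs(mean(m0b) - xb[1]), 0.02)
})

test_that("unoxidized palmitate leaves palmitate-phase breath at baseline", {
  tr <- zero_noise_truth(n_animals = 1, frac_oxidized = 0)
  br <- simulate_breath_series(tr$animals[1, ], default_protocols())
  d <- delta13c_from_currents(br$i44, br$i45, br$i46)
  ape <- ape_co2(d, d[br$timepoint_min == 0])
  expect_equal(ape[br$timepoint_min >= 140], rep(0, 3), tolerance = 1e-12)
})

test_that("citrate panels put label only on even isotopomers", {
  frag <- default_fragment_panel()$citrate
  cm <- na_correction_matrix(frag)
  pan <- simulate_citrate_panel(c(liver = 0.5), e_palmitate = 0.1,
                                frag = frag)
  mid <- correct_mid(pan$intensity, cm)$fractions
  expect_lt(max(abs(mid[c(2, 4, 6)])), 1e-9)     # M+1, M+3, M+5 empty
  expect_equal(sum(mid[-1]), 0.05, tolerance = 1e-9)
  # zero contribution leaves the corrected MID unlabelled
  pan0 <- simulate_citrate_panel(c(liver = 0), e_palmitate = 0.1,
                                 frag = frag)
  expect_equal(correct_mid(pan0$intensity, cm)$fractions,
               c(1, rep(0, 6)), tolerance = 1e-9)
})

test_that("clams photoperiod means recover the configured RER levels", {
  tr <- simulate_clams(n_per_group = 8, groups = "A", days = 2,
                       rer_light = 0.75, rer_dark = 0.85, seed = 31)
  ps <- photoperiod_summary(tr)
  dark <- ps$rer[ps$period == "dark"]
  light <- ps$rer[ps$period == "light"]
  expect_lt(abs(mean(dark) - 0.85), 3 * sem(dark) + 1e-3)
  expect_lt(abs(mean(light) - 0.75), 3 * sem(light) + 1e-3)
  expect_true(all(tr$vo2[tr$is_dark] |> mean() > mean(tr$vo2[!tr$is_dark])))
})

test_that("zero-noise study recovery is exact both ways", {
  truth <- zero_noise_truth(n_animals = 3)
  sim <- simulate_flux_study(truth)
  fit_c <- run_flux_study(sim$gcms, sim$breath, sim$animals,
                          config = flux_config(mode = "tracer_corrected"))
  fit_s <- run_flux_study(sim$gcms, sim$breath, sim$animals,
                          config = flux_config(mode = "simplified"))
  f_gly <- 2.5; f_palm <- 1.85
  # tracer-corrected recovers the endogenous rates
  expect_equal(fit_c$animals$ra_glycerol, truth$animals$ra_glycerol,
               tolerance = 1e-9)
  expect_equal(fit_c$animals$ra_palmitate, truth$animals$ra_palmitate,
               tolerance = 1e-9)
  # simplified recovers total turnover Ra + F
  expect_equal(fit_s$animals$ra_glycerol,
               truth$animals$ra_glycerol + f_gly, tolerance = 1e-9)
  expect_equal(fit_s$animals$ra_palmitate,
               truth$animals$ra_palmitate + f_palm, tolerance = 1e-9)
  # oxidation chain: fraction oxidized of total Rd, exactly
  expect_equal(fit_s$animals$fraction_oxidized, rep(0.30, 3),
               tolerance = 5e-3)
})
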