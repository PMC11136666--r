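# Synthetic-study generator: one-pool tracer kinetics, GC-MS intensities
# with multinomial natural-abundance structure, IRMS breath series and
# circadian chamber traces, all with known ground truth so the pipeline is
# testable by parameter recovery. All randomness flows from one study-level
# seed through per-animal derived seeds.

#' Ground truth for a simulated infusion study
#'
#' Defines the per-animal true rates the pipeline must recover. Rates are
#' drawn lognormally around the stated means with biological
#' between-animal coefficient of variation `between_animal_cv`
#' (mean-preserving). Defaults describe a fasted adult mouse: glycerol Ra
#' 30, palmitate Ra 15 and CO2 production 1500 nmol g^-1 min^-1, 30% of
#' palmitate disappearance oxidized, and tissue TCA fractional
#' contributions of palmitate between 0.2 and 0.6. Pool sizes (nmol/g) set
#' the one-pool time constants; the defaults put every plateau window many
#' time constants after its phase start.
#'
#' @param n_animals animals per group.
#' @param groups character vector of group labels.
#' @param ra_glycerol,ra_palmitate,ra_co2 mean endogenous rates of
#'   appearance, nmol g^-1 min^-1.
#' @param frac_oxidized fraction of palmitate disappearance oxidized.
#' @param tca_fractions named fractional TCA contributions per tissue.
#' @param pool_sizes named pool sizes (nmol/g) for `glycerol`, `palmitate`
#'   and `co2`.
#' @param group_effect named multiplicative effect per group applied to
#'   `ra_glycerol` and `ra_palmitate` (e.g. `c(A = 1, B = 0.7)`); groups
#'   without an entry get 1.
#' @param between_animal_cv biological cv of the per-animal true rates.
#' @param noise_cv multiplicative measurement noise cv applied by the
#'   generators.
#' @param seed study-level integer seed.
#' @return list of class `"simulation_truth"` with elements `animals`
#'   (tibble of per-animal true rates and a derived `animal_seed`),
#'   `tca_fractions`, `pool_sizes`, `noise_cv`, `seed`.
#' @export
simulation_truth <- function(n_animals = 5, groups = "A",
                             ra_glycerol = 30, ra_palmitate = 15,
                             ra_co2 = 1500, frac_oxidized = 0.30,
                             tca_fractions = c(liver = 0.60,
                                               gastrocnemius = 0.20,
                                               soleus = 0.35,
                                               diaphragm = 0.45),
                             pool_sizes = c(glycerol = 80, palmitate = 60,
                                            co2 = 1000),
                             group_effect = NULL,
                             between_animal_cv = 0.10,
                             noise_cv = 0.05, seed = 1L) {
  stopifnot(n_animals >= 1, ra_glycerol > 0, ra_palmitate > 0, ra_co2 > 0,
            frac_oxidized >= 0, frac_oxidized <= 1,
            all(tca_fractions >= 0), all(pool_sizes > 0),
            between_animal_cv >= 0, noise_cv >= 0)
  set.seed(as.integer(seed))
  grp <- rep(groups, each = n_animals)
  n <- length(grp)
  eff <- rep(1, n)
  if (!is.null(group_effect)) {
    hit <- grp %in% names(group_effect)
    eff[hit] <- group_effect[grp[hit]]
  }
  draw <- function(mu, n) {
    if (between_animal_cv == 0) return(rep(mu, n))
    s <- sqrt(log(1 + between_animal_cv^2))
    mu * exp(stats::rnorm(n, -s^2 / 2, s))
  }
  animals <- tibble::tibble(
    animal_id = sprintf("m%02d", seq_len(n)),
    group = grp,
    ra_glycerol = draw(ra_glycerol, n) * eff,
    ra_palmitate = draw(ra_palmitate, n) * eff,
    ra_co2 = draw(ra_co2, n),
    frac_oxidized = frac_oxidized,
    animal_seed = sample.int(.Machine$integer.max - 1L, n))
  structure(list(animals = animals, tca_fractions = tca_fractions,
                 pool_sizes = pool_sizes, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth>", nrow(x$animals), "animals, noise cv",
      x$noise_cv, ", seed", x$seed, "\n")
  print(x$animals)
  invisible(x)
}

# one-pool primed constant infusion response, deterministic part
one_pool_enrichment <- function(t, f, prime, ra_endogenous, pool_size,
                                start_min, end_min = Inf) {
  ra_total <- ra_endogenous + f
  k <- ra_total / pool_size
  e_ss <- f / ra_total
  e_prime <- prime / pool_size
  e <- numeric(length(t))
  # the sample drawn at t = start precedes the prime: baseline, zero excess
  during <- t > start_min & t <= end_min
  e[during] <- e_ss + (e_prime - e_ss) * exp(-k * (t[during] - start_min))
  after <- t > end_min
  if (any(after)) {
    e_end <- e_ss + (e_prime - e_ss) * exp(-k * (end_min - start_min))
    e[after] <- e_end * exp(-k * (t[after] - end_min))
  }
  e
}

#' Simulate a plasma enrichment time course
#'
#' One-pool fixed-volume turnover model for a primed constant infusion:
#' `E(t) = E_ss + (E_prime - E_ss) exp(-k (t - t_start))` with
#' `k = (Ra + F) / Q`, steady state `E_ss = F / (Ra + F)` (the tracer
#' contributes to total turnover) and prime response `E_prime = prime / Q`.
#' After the infusion window the enrichment decays with the same rate
#' constant. Multiplicative Gaussian noise with coefficient of variation
#' `noise_cv` is applied per sample.
#'
#' @param protocol one-row protocol tibble, see [tracer_protocol()].
#' @param ra_endogenous true endogenous tracee Ra, nmol g^-1 min^-1.
#' @param pool_size tracee pool size Q, nmol/g.
#' @param times sampling times (minutes, >= 0).
#' @param noise_cv multiplicative noise cv (0 = deterministic).
#' @param seed optional seed for the noise draw.
#' @return tibble with `timepoint_min`, `enrichment` (fraction, >= 0).
#' @export
simulate_enrichment_series <- function(protocol, ra_endogenous, pool_size,
                                       times, noise_cv = 0, seed = NULL) {
  stopifnot(nrow(protocol) == 1, ra_endogenous > 0, pool_size > 0)
  if (any(times < 0)) stop("negative sampling times", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  e <- one_pool_enrichment(times, protocol$rate_nmol_per_g_min,
                           protocol$prime_nmol_per_g, ra_endogenous,
                           pool_size, protocol$infusion_start_min,
                           protocol$infusion_end_min)
  if (noise_cv > 0) {
    e <- pmax(0, e * (1 + stats::rnorm(length(e), 0, noise_cv)))
  }
  tibble::tibble(timepoint_min = times, enrichment = pmin(e, 1))
}

# MID with fraction e on one labelled channel, remainder unlabelled
mid_from_label_enrichment <- function(e, label_index, n_channels) {
  x <- numeric(n_channels)
  x[1] <- 1 - e
  x[label_index + 1L] <- x[label_index + 1L] + e
  x
}

#' Simulate raw GC-MS channel intensities for a known MID
#'
#' Forward-convolves the true tracer MID through the natural-abundance
#' correction matrix of the fragment, scales to an arbitrary total
#' intensity, and applies per-channel multiplicative Gaussian noise.
#' [correct_mid()] on the zero-noise output recovers the truth.
#'
#' @param mid_truth true MID fraction vector (length `frag$n_channels`).
#' @param frag a [fragment()].
#' @param noise_cv per-channel multiplicative noise cv.
#' @param seed optional seed.
#' @param abundances see [isotope_abundances()].
#' @param total_intensity arbitrary total ion count to scale to.
#' @return tibble with `channel` (0-based) and `intensity`.
#' @export
simulate_gcms_intensities <- function(mid_truth, frag, noise_cv = 0,
                                      seed = NULL,
                                      abundances = isotope_abundances(),
                                      total_intensity = 1e6) {
  stopifnot(inherits(frag, "fragment"),
            length(mid_truth) == frag$n_channels,
            abs(sum(mid_truth) - 1) < 1e-6, all(mid_truth >= 0))
  if (!is.null(seed)) set.seed(seed)
  cm <- na_correction_matrix(frag, abundances)
  y <- as.vector(cm %*% mid_truth) * total_intensity
  if (noise_cv > 0) {
    y <- pmax(0, y * (1 + stats::rnorm(length(y), 0, noise_cv)))
  }
  tibble::tibble(channel = seq_len(frag$n_channels) - 1L, intensity = y)
}

#' Simulate a breath 13CO2 ion-current series
#'
#' Models the body CO2/bicarbonate pool as a single compartment. During
#' the bicarbonate phase the excess 13CO2 atom fraction approaches
#' `F_bicarb / (RaCO2 + F_bicarb)` with the prime response of the primed
#' infusion; during the palmitate phase it approaches
#' `n * frac_oxidized * F_palmitate / (RaCO2 + F_bicarb)` (the labelled
#' oxidation flux over total CO2 appearance) while the bicarbonate signal
#' washes out. A 13CO2 retention factor `retention_c` in (0, 1] scales the
#' pool equilibration rate constant only: transients slow down when label
#' is retained, but every plateau is unchanged — which is why the factor
#' cancels out of the steady-state oxidation estimate. The excess is
#' converted to delta-13C on top of a breath baseline and then to m/z
#' 44/45/46 ion currents via [currents_from_delta13c()].
#'
#' @param truth_animal one row of `simulation_truth()$animals` (needs
#'   `ra_co2`, `frac_oxidized`).
#' @param protocols protocol tibble containing the bicarbonate (`co2`) and
#'   palmitate rows.
#' @param times breath sampling times (minutes).
#' @param pool_co2 CO2/bicarbonate pool size, nmol/g.
#' @param noise_cv multiplicative noise cv applied to the excess
#'   enrichment per sample.
#' @param seed optional seed.
#' @param retention_c 13CO2 retention factor in (0, 1].
#' @param baseline_delta13c breath baseline delta-13C, per mil.
#' @param i44 m/z 44 current scale (arbitrary units).
#' @param ref IRMS constants, see [irms_reference()].
#' @return tibble with `timepoint_min`, `i44`, `i45`, `i46`.
#' @export
simulate_breath_series <- function(truth_animal, protocols,
                                   times = c(0, 50, 55, 60, 140, 145, 150),
                                   pool_co2 = 1000, noise_cv = 0,
                                   seed = NULL, retention_c = 1,
                                   baseline_delta13c = -20, i44 = 100,
                                   ref = irms_reference()) {
  stopifnot(retention_c > 0, retention_c <= 1)
  if (!is.null(seed)) set.seed(seed)
  bic <- protocols[protocols$analyte == "co2", ]
  palm <- protocols[protocols$analyte == "palmitate", ]
  if (nrow(bic) != 1 || nrow(palm) != 1) {
    stop("protocol table must define the bicarbonate and palmitate tracers",
         call. = FALSE)
  }
  ra_total <- truth_animal$ra_co2 + bic$rate_nmol_per_g_min
  k <- retention_c * ra_total / pool_co2
  t0 <- bic$infusion_start_min
  t1 <- bic$infusion_end_min
  e_ss_b <- bic$rate_nmol_per_g_min / ra_total
  e_prime <- bic$prime_nmol_per_g / pool_co2
  e_b <- numeric(length(times))
  during <- times > t0 & times <= t1
  e_b[during] <- e_ss_b + (e_prime - e_ss_b) * exp(-k * (times[during] - t0))
  after <- times > t1
  e_b_end <- e_ss_b + (e_prime - e_ss_b) * exp(-k * (t1 - t0))
  e_b[after] <- e_b_end * exp(-k * (times[after] - t1))
  # labelled 13CO2 from tracer palmitate oxidation: frac_ox of total
  # palmitate disappearance, of which the tracer fraction is E_palm_ss,
  # i.e. labelled oxidation = frac_ox * F_palm; times n labelled carbons
  e_p_ss <- palm$label_atom_count * truth_animal$frac_oxidized *
    palm$rate_nmol_per_g_min / ra_total
  e_p <- ifelse(times > palm$infusion_start_min,
                e_p_ss * (1 - exp(-k * (times - palm$infusion_start_min))), 0)
  excess <- e_b + e_p
  if (noise_cv > 0) {
    excess <- pmax(0, excess * (1 + stats::rnorm(length(excess), 0, noise_cv)))
  }
  af <- atom_fraction_13c(baseline_delta13c, ref$r13) + excess
  delta <- delta13c_from_atom_fraction(af, ref$r13)
  cur <- currents_from_delta13c(delta, i44 = i44, ref = ref)
  dplyr::bind_cols(tibble::tibble(timepoint_min = times), cur)
}

#' Simulate tissue citrate GC-MS panels
#'
#' For each tissue, places a total labelled citrate fraction of
#' `tca_fraction * e_palmitate` on the even mass shifts M+2, M+4 and M+6
#' with a geometric split (acetyl units from beta-oxidation enter the TCA
#' cycle two labelled carbons at a time; the geometric decay of higher
#' isotopomers is a simulator convention). Odd channels carry only
#' natural-abundance mass. The MID is forward-convolved and noised via
#' [simulate_gcms_intensities()].
#'
#' @param tca_fractions named vector of true fractional TCA contributions
#'   per tissue.
#' @param e_palmitate plasma palmitate plateau enrichment (fraction).
#' @param frag citrate [fragment()].
#' @param noise_cv,seed,abundances as in [simulate_gcms_intensities()].
#' @param split_ratio geometric ratio of successive even isotopomers.
#' @return tibble with `tissue`, `channel`, `intensity`.
#' @export
simulate_citrate_panel <- function(tca_fractions, e_palmitate,
                                   frag = default_fragment_panel()$citrate,
                                   noise_cv = 0, seed = NULL,
                                   abundances = isotope_abundances(),
                                   split_ratio = 0.3) {
  stopifnot(all(tca_fractions >= 0), e_palmitate > 0, e_palmitate <= 1,
            all(tca_fractions * e_palmitate <= 1))
  if (!is.null(seed)) set.seed(seed)
  even <- c(2L, 4L, 6L)
  even <- even[even < frag$n_channels]
  w <- split_ratio^(seq_along(even) - 1)
  w <- w / sum(w)
  purrr::map_dfr(names(tca_fractions), function(ts) {
    lab <- tca_fractions[[ts]] * e_palmitate
    mid <- numeric(frag$n_channels)
    mid[1] <- 1 - lab
    mid[even + 1L] <- lab * w
    dplyr::bind_cols(
      tibble::tibble(tissue = ts),
      simulate_gcms_intensities(mid, frag, noise_cv = noise_cv,
                                abundances = abundances))
  })
}

#' Simulate metabolic-chamber traces for two groups
#'
#' Circadian traces with a square-wave photoperiod (12 h light from t = 0,
#' 12 h dark) at the configured light/dark RER means plus a second-harmonic
#' sinusoid (zero mean within each photoperiod block, so block means stay
#' at the configured values), VO2 with a dark-phase boost, lognormal
#' between-animal variation and an optional multiplicative group effect,
#' and Poisson activity counts.
#'
#' @param n_per_group animals per group.
#' @param groups group labels.
#' @param days trace length in days.
#' @param dt_min sampling interval, minutes.
#' @param rer_light,rer_dark photoperiod RER means.
#' @param rer_wave amplitude of the within-block sinusoidal RER modulation.
#' @param vo2_l_per_h mean VO2 in litres per hour.
#' @param vo2_dark_boost fractional VO2 increase in the dark phase.
#' @param vo2_group_effect named multiplicative VO2 effect per group
#'   (groups without an entry get 1); 1 everywhere under the null.
#' @param activity_light,activity_dark Poisson means of activity counts
#'   per sample.
#' @param between_animal_cv lognormal cv of per-animal VO2 level.
#' @param sample_cv multiplicative per-sample noise cv on VO2 and VCO2.
#' @param seed integer seed.
#' @return tibble with `animal_id`, `group`, `timestamp_min`, `vo2`,
#'   `vco2`, `x_total`, `is_dark`.
#' @export
simulate_clams <- function(n_per_group = 8, groups = c("A", "B"), days = 5,
                           dt_min = 30, rer_light = 0.75, rer_dark = 0.85,
                           rer_wave = 0.02, vo2_l_per_h = 0.10,
                           vo2_dark_boost = 0.15, vo2_group_effect = NULL,
                           activity_light = 10, activity_dark = 40,
                           between_animal_cv = 0.08, sample_cv = 0.03,
                           seed = 1L) {
  stopifnot(n_per_group >= 1, days > 0, dt_min > 0)
  set.seed(as.integer(seed))
  times <- seq(0, days * 1440 - dt_min, by = dt_min)
  is_dark <- (times %% 1440) >= 720
  s_b <- sqrt(log(1 + between_animal_cv^2))
  purrr::map_dfr(groups, function(g) {
    eff <- if (!is.null(vo2_group_effect) && g %in% names(vo2_group_effect)) {
      vo2_group_effect[[g]]
    } else 1
    purrr::map_dfr(seq_len(n_per_group), function(i) {
      lvl <- vo2_l_per_h * eff *
        if (between_animal_cv > 0) exp(stats::rnorm(1, -s_b^2 / 2, s_b)) else 1
      vo2 <- lvl * (1 + vo2_dark_boost * is_dark) *
        (1 + stats::rnorm(length(times), 0, sample_cv))
      r <- ifelse(is_dark, rer_dark, rer_light) +
        rer_wave * sin(2 * pi * times / 720)
      vco2 <- r * vo2 * (1 + stats::rnorm(length(times), 0, sample_cv))
      tibble::tibble(animal_id = sprintf("%s%02d", g, i), group = g,
                     timestamp_min = times, vo2 = pmax(vo2, 1e-6),
                     vco2 = pmax(vco2, 0),
                     x_total = stats::rpois(length(times),
                                            ifelse(is_dark, activity_dark,
                                                   activity_light)),
                     is_dark = is_dark)
    })
  })
}

#' Simulate a complete infusion study
#'
#' Generates every input table [run_flux_study()] consumes — plasma GC-MS
#' intensities, breath ion currents, tissue citrate panels and the animal
#' table — from a [simulation_truth()]. Each animal's data are generated
#' under its own derived seed.
#'
#' @param truth a [simulation_truth()].
#' @param protocols protocol tibble, see [default_protocols()].
#' @param panel fragment panel, see [default_fragment_panel()].
#' @param abundances see [isotope_abundances()].
#' @param times_plasma,times_breath sampling schedules (minutes).
#' @param retention_c 13CO2 retention factor passed to
#'   [simulate_breath_series()].
#' @param baseline_delta13c breath baseline delta-13C, per mil.
#' @return list of class `"flux_study_sim"`: `gcms`, `breath`, `tissue`,
#'   `animals`, `truth`.
#' @export
simulate_flux_study <- function(truth = simulation_truth(),
                                protocols = default_protocols(),
                                panel = default_fragment_panel(),
                                abundances = isotope_abundances(),
                                times_plasma = c(0, 160, 170, 180),
                                times_breath = c(0, 50, 55, 60, 140, 145, 150),
                                retention_c = 1,
                                baseline_delta13c = -20) {
  stopifnot(inherits(truth, "simulation_truth"))
  noise <- truth$noise_cv
  pools <- truth$pool_sizes
  plasma_protocols <- protocols[protocols$matrix == "plasma", ]
  rows <- purrr::map(seq_len(nrow(truth$animals)), function(i) {
    an <- truth$animals[i, ]
    set.seed(an$animal_seed)
    e_palm_ss <- NULL
    gcms <- purrr::map_dfr(seq_len(nrow(plasma_protocols)), function(j) {
      pr <- plasma_protocols[j, ]
      ra_true <- an[[paste0("ra_", pr$analyte)]]
      series <- simulate_enrichment_series(pr, ra_true, pools[[pr$analyte]],
                                           times_plasma, noise_cv = noise)
      frag <- panel[[pr$analyte]]
      purrr::map_dfr(seq_len(nrow(series)), function(k) {
        mid <- mid_from_label_enrichment(series$enrichment[k],
                                         frag$n_label_positions,
                                         frag$n_channels)
        dplyr::bind_cols(
          tibble::tibble(animal_id = an$animal_id, analyte = pr$analyte,
                         timepoint_min = series$timepoint_min[k]),
          simulate_gcms_intensities(mid, frag, noise_cv = noise,
                                    abundances = abundances))
      })
    })
    breath <- dplyr::bind_cols(
      tibble::tibble(animal_id = an$animal_id),
      simulate_breath_series(an, protocols, times = times_breath,
                             pool_co2 = pools[["co2"]], noise_cv = noise,
                             retention_c = retention_c,
                             baseline_delta13c = baseline_delta13c))
    palm <- protocols[protocols$analyte == "palmitate", ]
    e_palm_ss <- palm$rate_nmol_per_g_min /
      (an$ra_palmitate + palm$rate_nmol_per_g_min)
    tissue <- dplyr::bind_cols(
      tibble::tibble(animal_id = an$animal_id, analyte = "citrate",
                     timepoint_min = max(times_plasma)),
      simulate_citrate_panel(truth$tca_fractions, e_palm_ss,
                             frag = panel$citrate, noise_cv = noise,
                             abundances = abundances))
    list(gcms = gcms, breath = breath, tissue = tissue)
  })
  structure(list(
    gcms = purrr::map_dfr(rows, "gcms"),
    breath = purrr::map_dfr(rows, "breath"),
    tissue = purrr::map_dfr(rows, "tissue"),
    animals = truth$animals[, c("animal_id", "group")],
    truth = truth), class = "flux_study_sim")
}
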