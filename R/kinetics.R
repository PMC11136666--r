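# Steady-state tracer kinetics: plateau estimation and dilution equations.
# All rates are nmol per g body weight per minute.

plateau_one <- function(t, e, cv_max = 0.10, slope_alpha = 0.05) {
  n <- length(t)
  if (n < 2) stop("plateau estimation needs >= 2 points in the window",
                  call. = FALSE)
  m <- mean(e)
  cv <- if (m > 0) stats::sd(e) / m else 0
  fit <- stats::lm(e ~ t)
  slope <- unname(stats::coef(fit)[2])
  sm <- suppressWarnings(summary(fit))$coefficients
  slope_se <- sm[2, 2]
  if (!is.finite(slope_se) || slope_se <= .Machine$double.eps * max(abs(e), 1)) {
    # perfectly collinear points (e.g. zero-noise plateau): judge the slope
    # by its effect across the window relative to the mean
    drift <- abs(slope) * (max(t) - min(t))
    slope_p <- NA_real_
    slope_ok <- m <= 0 || drift <= 1e-6 * max(m, .Machine$double.eps)
  } else {
    slope_p <- sm[2, 4]
    slope_ok <- slope_p >= slope_alpha
  }
  tibble::tibble(mean_enrichment = m, cv = cv, slope_per_min = slope,
                 slope_p = slope_p, n_points = n,
                 steady = cv <= cv_max && slope_ok)
}

#' Estimate plateau enrichment over a sampling window
#'
#' For each series (grouping defined by every column other than
#' `timepoint_min` and `enrichment`), restricts to points inside the window
#' and returns the mean enrichment, its coefficient of variation, the
#' least-squares slope, and a steadiness verdict: steady when
#' `cv <= cv_max` and the slope is not significantly different from zero at
#' `slope_alpha` (for numerically exact plateaus, where the regression has
#' zero residual, the slope is instead required to move the window by less
#' than one part in 1e6 of the mean). Enrichments are assumed already
#' baseline-subtracted.
#'
#' @param series tibble with columns `timepoint_min` and `enrichment`
#'   (fractions); any other columns define the series grouping
#'   (e.g. `animal_id`, `analyte`).
#' @param window numeric `(start, end)` in minutes, inclusive.
#' @param cv_max maximum coefficient of variation for steadiness.
#' @param slope_alpha significance level of the zero-slope test.
#' @return tibble with one row per series: grouping columns plus
#'   `mean_enrichment`, `cv`, `slope_per_min`, `slope_p`, `n_points`,
#'   `steady`.
#' @examples
#' estimate_plateau(
#'   tibble::tibble(timepoint_min = c(160, 170, 180),
#'                  enrichment = c(0.05, 0.05, 0.05)),
#'   window = c(160, 180))
#' @export
estimate_plateau <- function(series, window = c(160, 180),
                             cv_max = 0.10, slope_alpha = 0.05) {
  check_columns(series, c("timepoint_min", "enrichment"), "enrichment series")
  stopifnot(length(window) == 2, window[2] > window[1])
  keys <- setdiff(names(series), c("timepoint_min", "enrichment"))
  inside <- series |>
    dplyr::filter(.data$timepoint_min >= window[1],
                  .data$timepoint_min <= window[2])
  if (length(keys) == 0) {
    return(plateau_one(inside$timepoint_min, inside$enrichment,
                       cv_max, slope_alpha))
  }
  inside |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ plateau_one(.x$timepoint_min, .x$enrichment,
                                      cv_max, slope_alpha)) |>
    dplyr::ungroup()
}

#' Steady-state rate of appearance by tracer dilution
#'
#' At isotopic steady state the tracee rate of appearance equals its rate
#' of disappearance, and the infusion rate divided by the plateau
#' enrichment measures turnover. Two conventions are provided:
#' \describe{
#'   \item{simplified (default)}{`Ra = F / E`; this is total turnover and
#'     overestimates endogenous appearance by exactly `F`.}
#'   \item{tracer_corrected}{`Ra = F * (1 / E - 1)`, the endogenous rate
#'     with the tracer's own contribution removed.}
#' }
#'
#' @param f tracer infusion rate, nmol g^-1 min^-1 (> 0), vectorized.
#' @param e_plateau plateau enrichment fraction in (0, 1].
#' @param mode `"simplified"` or `"tracer_corrected"`.
#' @return Ra (= Rd) in nmol g^-1 min^-1.
#' @examples
#' ra_steady_state(2.5, 0.05)                            # 50
#' ra_steady_state(2.5, 0.05, mode = "tracer_corrected") # 47.5
#' @export
ra_steady_state <- function(f, e_plateau,
                            mode = c("simplified", "tracer_corrected")) {
  mode <- match.arg(mode)
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("infusion rate F must be positive", call. = FALSE)
  }
  if (any(!is.finite(e_plateau)) || any(e_plateau <= 0)) {
    stop("plateau enrichment must be positive (infinite dilution otherwise)",
         call. = FALSE)
  }
  if (mode == "simplified") f / e_plateau else f * (1 / e_plateau - 1)
}

#' Whole-body CO2 appearance rate from bicarbonate dilution
#'
#' `RaCO2 = F_bicarbonate / ECO2` at the bicarbonate-phase breath plateau
#' (50-60 min by default in the packaged protocol).
#'
#' @param f_bicarbonate bicarbonate tracer infusion rate, nmol g^-1 min^-1.
#' @param eco2_plateau breath 13CO2 atom fraction excess at plateau (> 0).
#' @return RaCO2 in nmol g^-1 min^-1.
#' @examples
#' ra_co2(0.15, 0.0001)
#' @export
ra_co2 <- function(f_bicarbonate, eco2_plateau) {
  if (any(!is.finite(eco2_plateau)) || any(eco2_plateau <= 0)) {
    stop("bicarbonate-phase CO2 enrichment must be positive", call. = FALSE)
  }
  if (any(f_bicarbonate <= 0)) {
    stop("bicarbonate infusion rate must be positive", call. = FALSE)
  }
  f_bicarbonate / eco2_plateau
}

#' Palmitate oxidation rate anchored on bicarbonate dilution
#'
#' `Rox = RaCO2 * ECO2(palmitate phase) / (E_palmitate * n)`, with `n = 16`
#' labelled carbons for uniformly labelled palmitate. The conventional
#' formula multiplies breath enrichment by VCO2 and divides by a 13CO2
#' recovery factor `C`; replacing VCO2 with `RaCO2 * C` makes `C` cancel,
#' so no retention assumption is needed.
#'
#' @param ra_co2 CO2 appearance rate from [ra_co2()], nmol g^-1 min^-1.
#' @param eco2_palmitate breath 13CO2 atom fraction excess at the
#'   palmitate-phase plateau (140-150 min by default).
#' @param e_palmitate plasma palmitate plateau enrichment fraction (> 0).
#' @param n_label_atoms labelled carbons per tracer molecule (default 16).
#' @return oxidation rate in nmol g^-1 min^-1.
#' @examples
#' palmitate_oxidation(1500, 0.0008, 0.05)  # 1.5
#' @export
palmitate_oxidation <- function(ra_co2, eco2_palmitate, e_palmitate,
                                n_label_atoms = 16) {
  if (any(!is.finite(e_palmitate)) || any(e_palmitate <= 0)) {
    stop("plasma palmitate enrichment must be positive", call. = FALSE)
  }
  if (any(n_label_atoms < 1)) {
    stop("n_label_atoms must be >= 1", call. = FALSE)
  }
  if (any(eco2_palmitate < 0)) {
    stop("breath enrichment must be non-negative", call. = FALSE)
  }
  ra_co2 * eco2_palmitate / (e_palmitate * n_label_atoms)
}

#' Fraction of palmitate disappearance that is oxidized
#'
#' `Rox / Rd`. Values above 1 are physiologically impossible and trigger a
#' warning (QC flag downstream), not an error.
#'
#' @param rox palmitate oxidation rate.
#' @param rd palmitate rate of disappearance (> 0).
#' @return fraction (>= 0), vectorized.
#' @export
fraction_oxidized <- function(rox, rd) {
  if (any(!is.finite(rd)) || any(rd <= 0)) {
    stop("Rd must be positive", call. = FALSE)
  }
  out <- rox / rd
  if (any(out > 1)) {
    warning("fraction oxidized exceeds 1; check enrichments", call. = FALSE)
  }
  out
}

#' Fractional contribution of palmitate to tissue TCA-cycle flux
#'
#' Total labelled citrate enrichment (sum of M+1..M+6) normalized by the
#' plasma palmitate plateau enrichment of the same animal.
#'
#' @param citrate_total_enrichment total labelled citrate fraction.
#' @param e_palmitate plasma palmitate enrichment fraction (> 0).
#' @return fractional contribution (>= 0), vectorized.
#' @examples
#' fractional_tca_contribution(0.02, 0.10)  # 0.2
#' @export
fractional_tca_contribution <- function(citrate_total_enrichment,
                                        e_palmitate) {
  if (any(!is.finite(e_palmitate)) || any(e_palmitate <= 0)) {
    stop("plasma palmitate enrichment must be positive", call. = FALSE)
  }
  if (any(citrate_total_enrichment < 0)) {
    stop("citrate enrichment must be non-negative", call. = FALSE)
  }
  citrate_total_enrichment / e_palmitate
}
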