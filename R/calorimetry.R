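# Indirect calorimetry: RER, energy expenditure, photoperiod summaries.

#' Respiratory exchange ratio
#'
#' `RER = VCO2 / VO2`. Near 0.7 on pure fat oxidation, near 1.0 on pure
#' carbohydrate oxidation.
#'
#' @param vco2,vo2 gas exchange rates in matching volume-per-time units;
#'   `vo2` must be positive. Vectorized.
#' @return dimensionless ratio.
#' @export
rer <- function(vco2, vo2) {
  if (any(!is.finite(vo2)) || any(vo2 <= 0)) {
    stop("VO2 must be positive", call. = FALSE)
  }
  if (any(vco2 < 0)) stop("VCO2 must be non-negative", call. = FALSE)
  vco2 / vo2
}

#' Energy expenditure from VO2 and RER
#'
#' `EE = (3.815 + 1.232 * RER) * VO2`. With VO2 in litres per hour the
#' result is kcal per hour (the caloric equivalent of oxygen,
#' 3.815-5.047 kcal per litre O2 across the RER range). Chamber exports in
#' ml kg^-1 h^-1 should be converted first, see [vo2_to_l_per_h()].
#'
#' @param rer respiratory exchange ratio; values outside `[0.7, 1.0]` are
#'   physiologically unusual and warn, values outside `[0, 1.3]` error.
#' @param vo2 oxygen consumption in litres per hour (>= 0). Vectorized.
#' @return energy expenditure in kcal per hour.
#' @examples
#' energy_expenditure(0.7, 3.0)  # 14.0292
#' @export
energy_expenditure <- function(rer, vo2) {
  if (any(!is.finite(rer)) || any(rer < 0) || any(rer > 1.3)) {
    stop("RER must lie in [0, 1.3]", call. = FALSE)
  }
  if (any(!is.finite(vo2)) || any(vo2 < 0)) {
    stop("VO2 must be non-negative", call. = FALSE)
  }
  if (any(rer < 0.7 | rer > 1.0)) {
    warning("RER outside the physiological range [0.7, 1.0]", call. = FALSE)
  }
  (3.815 + 1.232 * rer) * vo2
}

#' Convert mass-normalized VO2 to litres per hour
#'
#' Metabolic chambers commonly export gas exchange as ml kg^-1 h^-1; the
#' energy-expenditure formula expects L h^-1 for a kcal h^-1 result.
#'
#' @param vol_ml_per_kg_h gas volume in ml per kg body mass per hour.
#' @param body_mass_g animal body mass in grams.
#' @return volume in litres per hour.
#' @export
vo2_to_l_per_h <- function(vol_ml_per_kg_h, body_mass_g) {
  stopifnot(all(body_mass_g > 0))
  vol_ml_per_kg_h * (body_mass_g / 1000) / 1000
}

#' Photoperiod summary of a metabolic-chamber trace
#'
#' Per animal, averages RER, VO2, VCO2 and energy expenditure over the
#' light samples, the dark samples and the full trace, and sums activity
#' counts. Sample counts are conserved: `n(light) + n(dark) = n(overall)`.
#'
#' @param trace tibble with columns `animal_id`, `timestamp_min`, `vo2`
#'   (L/h), `vco2` (L/h), `x_total` (activity counts) and `is_dark`
#'   (logical); an optional `group` column is carried through.
#' @return tibble with one row per animal x period
#'   (`"light"`, `"dark"`, `"overall"`): mean `rer`, `vo2`, `vco2`,
#'   `ee_kcal_h`, summed `activity_counts`, and `n_samples`.
#' @export
photoperiod_summary <- function(trace) {
  check_columns(trace, c("animal_id", "timestamp_min", "vo2", "vco2",
                         "x_total", "is_dark"), "calorimetry trace")
  if (nrow(trace) == 0) stop("empty calorimetry trace", call. = FALSE)
  keys <- intersect(c("animal_id", "group"), names(trace))
  aug <- trace |>
    dplyr::mutate(rer = rer(.data$vco2, .data$vo2),
                  ee_kcal_h = (3.815 + 1.232 * .data$rer) * .data$vo2)
  one <- function(d) {
    tibble::tibble(rer = mean(d$rer), vo2 = mean(d$vo2),
                   vco2 = mean(d$vco2), ee_kcal_h = mean(d$ee_kcal_h),
                   activity_counts = sum(d$x_total), n_samples = nrow(d))
  }
  periods <- list(light = function(d) d[!d$is_dark, ],
                  dark = function(d) d[d$is_dark, ],
                  overall = function(d) d)
  aug |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, g) {
      dplyr::bind_rows(lapply(names(periods), function(p) {
        sub <- periods[[p]](d)
        if (nrow(sub) == 0) return(NULL)
        dplyr::bind_cols(tibble::tibble(period = p), one(sub))
      }))
    }) |>
    dplyr::ungroup()
}

#' Plot a metabolic-chamber trace
#'
#' RER and energy expenditure against time with dark periods shaded.
#'
#' @param trace as in [photoperiod_summary()].
#' @return a ggplot object.
#' @export
plot_calorimetry <- function(trace) {
  check_columns(trace, c("animal_id", "timestamp_min", "vo2", "vco2",
                         "is_dark"), "calorimetry trace")
  long <- trace |>
    dplyr::mutate(RER = rer(.data$vco2, .data$vo2),
                  `EE (kcal/h)` = (3.815 + 1.232 * .data$RER) * .data$vo2) |>
    tidyr::pivot_longer(c("RER", "EE (kcal/h)"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$timestamp_min / 60, .data$value,
                                     group = .data$animal_id)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}
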