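# Enrichment measures. All enrichments are dimensionless mole/atom
# fractions internally; multiply by 100 only at reporting boundaries
# (mole percent excess, atom percent excess).

#' Mole fraction excess at one mass isotopomer
#'
#' Baseline-subtracted mole fraction of the analyte at a given mass shift:
#' `max(0, sample[m] - baseline[m])`. Reported at I/O boundaries as mole
#' percent excess (x 100); carried here as a fraction.
#'
#' @param sample,baseline corrected MID fraction vectors of equal length
#'   (M+0 first).
#' @param label_index mass shift of interest (e.g. 16 for \[U-13C16\]
#'   palmitate, 5 for d5-glycerol).
#' @return excess mole fraction in `[0, 1]`.
#' @examples
#' enrichment_mpe(c(0.938, 0, 0, 0, 0, 0.062), c(0.988, 0, 0, 0, 0, 0.012), 5)
#' @export
enrichment_mpe <- function(sample, baseline, label_index) {
  if (length(sample) != length(baseline)) {
    stop("sample and baseline MIDs have different channel counts",
         call. = FALSE)
  }
  label_index <- as.integer(label_index)
  if (label_index < 0 || label_index >= length(sample)) {
    stop("label_index out of range", call. = FALSE)
  }
  max(0, sample[label_index + 1L] - baseline[label_index + 1L])
}

#' Total labelled enrichment of a corrected MID
#'
#' Sum over all mass shifts m >= 1 of the baseline-subtracted fractions,
#' each clipped at zero. With an unlabelled baseline `(1, 0, ..., 0)` this
#' equals `1 - sample[M+0]`. Used for total citrate enrichment
#' (sum of M+1 to M+6).
#'
#' @inheritParams enrichment_mpe
#' @return fraction in `[0, 1]`.
#' @export
total_labeled_enrichment <- function(sample, baseline) {
  if (length(sample) != length(baseline)) {
    stop("sample and baseline MIDs have different channel counts",
         call. = FALSE)
  }
  sum(pmax(0, sample[-1] - baseline[-1]))
}

#' IRMS reference constants for breath CO2
#'
#' Isotope-ratio constants used to convert m/z 44/45/46 ion currents to
#' delta-13C and atom fraction. Defaults: `r13 = 0.011180` (VPDB 13C/12C),
#' `r17 = 0.000393` and `r18 = 0.002088` (VPDB-CO2 17O/16O and 18O/16O),
#' and mass-dependent fractionation exponent `lambda = 0.516` relating 17O
#' to 18O variation. All are overridable.
#'
#' @param r13,r17,r18 reference isotope ratios (> 0).
#' @param lambda 17O/18O mass-dependence exponent.
#' @return named list of constants.
#' @export
irms_reference <- function(r13 = 0.011180, r17 = 0.000393,
                           r18 = 0.002088, lambda = 0.516) {
  stopifnot(r13 > 0, r17 > 0, r18 > 0, lambda > 0)
  list(r13 = r13, r17 = r17, r18 = r18, lambda = lambda)
}

#' Convert CO2 ion currents to delta-13C
#'
#' From ion currents at m/z 44 (12C16O2), 45 (13C16O2 + 12C17O16O) and 46
#' (mostly 12C18O16O), computes delta-13C per mil against the reference
#' with a Craig-type 17O correction: the 18O ratio is taken as
#' `R46 / 2`, the 17O ratio follows mass-dependent scaling
#' `r17 * (R18 / r18) ^ lambda`, and the 13C ratio is `R45 - 2 * R17`.
#'
#' @param i44,i45,i46 non-negative ion currents (arbitrary units),
#'   vectorized; `i44` must be positive.
#' @param ref constants from [irms_reference()].
#' @return delta-13C in per mil, same length as the inputs.
#' @seealso [currents_from_delta13c()] for the exact inverse used by the
#'   simulator.
#' @export
delta13c_from_currents <- function(i44, i45, i46, ref = irms_reference()) {
  if (any(!is.finite(i44)) || any(i44 <= 0)) {
    stop("i44 must be positive", call. = FALSE)
  }
  if (any(i45 < 0) || any(i46 < 0)) {
    stop("ion currents must be non-negative", call. = FALSE)
  }
  r45 <- i45 / i44
  r46 <- i46 / i44
  r18 <- r46 / 2
  r17 <- ref$r17 * (r18 / ref$r18)^ref$lambda
  r13 <- r45 - 2 * r17
  (r13 / ref$r13 - 1) * 1000
}

#' Synthesize CO2 ion currents for a given delta-13C
#'
#' Exact algebraic inverse of [delta13c_from_currents()], used by the
#' breath simulator: the sample's oxygen isotopes are placed at the
#' reference composition shifted by `delta18o` per mil, and m/z 45 carries
#' the 13C and 17O contributions.
#'
#' @param delta13c delta-13C per mil (vectorized).
#' @param i44 m/z 44 current to scale to (default 1).
#' @param delta18o sample delta-18O per mil (default 0).
#' @param ref constants from [irms_reference()].
#' @return tibble with columns `i44`, `i45`, `i46`.
#' @export
currents_from_delta13c <- function(delta13c, i44 = 1, delta18o = 0,
                                   ref = irms_reference()) {
  r13 <- ref$r13 * (1 + delta13c / 1000)
  r18 <- ref$r18 * (1 + delta18o / 1000)
  r17 <- ref$r17 * (r18 / ref$r18)^ref$lambda
  tibble::tibble(i44 = i44,
                 i45 = i44 * (r13 + 2 * r17),
                 i46 = i44 * 2 * r18)
}

#' Atom fraction of 13C at a given delta-13C
#'
#' `AF = R / (1 + R)` with `R = r13 * (1 + delta / 1000)`.
#'
#' @param delta13c delta-13C per mil.
#' @param r13 standard 13C/12C ratio.
#' @return atom fraction in `[0, 1]`.
#' @export
atom_fraction_13c <- function(delta13c, r13 = 0.011180) {
  r <- r13 * (1 + delta13c / 1000)
  r / (1 + r)
}

#' Atom fraction excess of breath 13CO2
#'
#' Excess 13C atom fraction of expired CO2 over the baseline sample,
#' clipped at zero. Reported at I/O boundaries as atom percent excess
#' (x 100).
#'
#' @param delta_sample,delta_baseline delta-13C per mil.
#' @param r13_standard standard 13C/12C ratio.
#' @return excess atom fraction (>= 0), vectorized.
#' @examples
#' ape_co2(10, -20)
#' @export
ape_co2 <- function(delta_sample, delta_baseline, r13_standard = 0.011180) {
  stopifnot(r13_standard > 0)
  pmax(0, atom_fraction_13c(delta_sample, r13_standard) -
         atom_fraction_13c(delta_baseline, r13_standard))
}

# inverse of atom_fraction_13c, used by the breath simulator
delta13c_from_atom_fraction <- function(af, r13 = 0.011180) {
  r <- af / (1 - af)
  (r / r13 - 1) * 1000
}
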