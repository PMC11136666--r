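# Tracer protocol definitions and study configuration.
# Doses are nmol per g body weight (prime) and nmol per g per minute
# (infusion rate): the protocol's "nM per gram" is read as amount per gram,
# since a molar concentration cannot prime a pool per unit body weight.

#' Define a tracer infusion protocol
#'
#' @param tracer tracer name, e.g. `"[1-13C]bicarbonate"`.
#' @param analyte plasma/breath analyte the tracer is read out on
#'   (`"co2"`, `"palmitate"`, `"glycerol"`).
#' @param label_atom_count labelled atoms per tracer molecule (16 for
#'   \[U-13C16\]palmitate, 5 for d5-glycerol, 1 for bicarbonate).
#' @param prime_nmol_per_g priming bolus, nmol per g body weight (>= 0).
#' @param rate_nmol_per_g_min constant infusion rate, nmol g^-1 min^-1
#'   (> 0).
#' @param infusion_start_min,infusion_end_min infusion window, minutes from
#'   the start of the study (bicarbonate start = 0).
#' @param plateau_start_min,plateau_end_min sampling window used for the
#'   plateau estimate; must lie inside the phase it targets.
#' @param matrix where the enrichment is measured: `"breath"`, `"plasma"`
#'   or `"tissue"`.
#' @return one-row tibble.
#' @export
tracer_protocol <- function(tracer, analyte, label_atom_count,
                            prime_nmol_per_g, rate_nmol_per_g_min,
                            infusion_start_min, infusion_end_min,
                            plateau_start_min, plateau_end_min,
                            matrix = c("plasma", "breath", "tissue")) {
  matrix <- match.arg(matrix)
  stopifnot(label_atom_count >= 1, prime_nmol_per_g >= 0,
            rate_nmol_per_g_min > 0,
            infusion_end_min > infusion_start_min,
            plateau_end_min > plateau_start_min)
  tibble::tibble(
    tracer = tracer, analyte = analyte,
    label_atom_count = as.integer(label_atom_count),
    prime_nmol_per_g = as.numeric(prime_nmol_per_g),
    rate_nmol_per_g_min = as.numeric(rate_nmol_per_g_min),
    infusion_start_min = as.numeric(infusion_start_min),
    infusion_end_min = as.numeric(infusion_end_min),
    plateau_start_min = as.numeric(plateau_start_min),
    plateau_end_min = as.numeric(plateau_end_min),
    matrix = matrix)
}

#' Packaged infusion protocol
#'
#' The two-phase primed constant infusion: \[1-13C\]bicarbonate
#' (prime 12.75 nmol/g, 0.15 nmol/g/min) for 0-60 min with breath sampling
#' at 50-60 min; then \[U-13C16\]palmitate (1.85 nmol/g/min) and
#' \[1,1,2,3,3-d5\]glycerol (2.5 nmol/g/min) for 60-180 min, with
#' palmitate-phase breath sampling at 140-150 min and plasma sampling at
#' 160-180 min.
#'
#' @return tibble with one row per tracer (see [tracer_protocol()]).
#' @export
default_protocols <- function() {
  dplyr::bind_rows(
    tracer_protocol("[1-13C]bicarbonate", "co2", 1,
                    prime_nmol_per_g = 12.75, rate_nmol_per_g_min = 0.15,
                    infusion_start_min = 0, infusion_end_min = 60,
                    plateau_start_min = 50, plateau_end_min = 60,
                    matrix = "breath"),
    tracer_protocol("[U-13C16]palmitate", "palmitate", 16,
                    prime_nmol_per_g = 0, rate_nmol_per_g_min = 1.85,
                    infusion_start_min = 60, infusion_end_min = 180,
                    plateau_start_min = 160, plateau_end_min = 180,
                    matrix = "plasma"),
    tracer_protocol("[1,1,2,3,3-d5]glycerol", "glycerol", 5,
                    prime_nmol_per_g = 0, rate_nmol_per_g_min = 2.5,
                    infusion_start_min = 60, infusion_end_min = 180,
                    plateau_start_min = 160, plateau_end_min = 180,
                    matrix = "plasma")
  )
}

#' Study configuration
#'
#' Bundles protocols, fragment panel, QC thresholds, mode flags and the
#' seed into one validated object consumed by [run_flux_study()] and the
#' command-line interface.
#'
#' @param protocols tibble from [default_protocols()] / [tracer_protocol()].
#' @param panel fragment panel, see [default_fragment_panel()].
#' @param breath_palmitate_window breath sampling window (min) used for the
#'   palmitate-phase 13CO2 plateau.
#' @param cv_max,slope_alpha plateau steadiness thresholds, see
#'   [estimate_plateau()].
#' @param residual_threshold MID correction residual QC threshold.
#' @param mode Ra convention, see [ra_steady_state()].
#' @param washout_rate_per_min optional rate constant of a mono-exponential
#'   bicarbonate 13CO2 washout subtracted from palmitate-phase breath
#'   enrichment; `NULL` (default) applies no correction.
#' @param sampling_times_plasma,sampling_times_breath nominal sampling
#'   schedules in minutes, used for validation and by the simulator.
#' @param seed integer seed for any stochastic step.
#' @return list of class `"flux_config"`.
#' @export
flux_config <- function(protocols = default_protocols(),
                        panel = default_fragment_panel(),
                        breath_palmitate_window = c(140, 150),
                        cv_max = 0.10, slope_alpha = 0.05,
                        residual_threshold = 0.05,
                        mode = c("simplified", "tracer_corrected"),
                        washout_rate_per_min = NULL,
                        sampling_times_plasma = c(0, 160, 170, 180),
                        sampling_times_breath = c(0, 50, 55, 60, 140, 145, 150),
                        seed = 1L) {
  mode <- match.arg(mode)
  check_columns(protocols,
                c("tracer", "analyte", "label_atom_count",
                  "prime_nmol_per_g", "rate_nmol_per_g_min",
                  "infusion_start_min", "infusion_end_min",
                  "plateau_start_min", "plateau_end_min", "matrix"),
                "protocol table")
  if (anyDuplicated(protocols$analyte)) {
    stop("each analyte must be defined exactly once in the protocol table",
         call. = FALSE)
  }
  bad <- protocols$plateau_start_min < protocols$infusion_start_min |
    protocols$plateau_end_min > protocols$infusion_end_min
  if (any(bad)) {
    stop("plateau window outside the infusion phase for tracer(s): ",
         paste(protocols$tracer[bad], collapse = ", "), call. = FALSE)
  }
  plasma <- protocols[protocols$matrix == "plasma", ]
  covered <- vapply(seq_len(nrow(plasma)), function(i) {
    sum(sampling_times_plasma >= plasma$plateau_start_min[i] &
          sampling_times_plasma <= plasma$plateau_end_min[i]) >= 2
  }, logical(1))
  if (any(!covered)) {
    stop("plateau window of ", paste(plasma$tracer[!covered], collapse = ", "),
         " covers fewer than 2 plasma sampling times", call. = FALSE)
  }
  structure(list(
    protocols = protocols, panel = panel,
    breath_palmitate_window = as.numeric(breath_palmitate_window),
    cv_max = cv_max, slope_alpha = slope_alpha,
    residual_threshold = residual_threshold,
    mode = mode, washout_rate_per_min = washout_rate_per_min,
    sampling_times_plasma = as.numeric(sampling_times_plasma),
    sampling_times_breath = as.numeric(sampling_times_breath),
    seed = as.integer(seed)), class = "flux_config")
}

#' @export
print.flux_config <- function(x, ...) {
  cat("<flux_config> mode =", x$mode, ", seed =", x$seed, "\n")
  print(x$protocols[, c("tracer", "analyte", "prime_nmol_per_g",
                        "rate_nmol_per_g_min", "plateau_start_min",
                        "plateau_end_min", "matrix")])
  invisible(x)
}

#' Read and validate a study configuration file
#'
#' Parses a YAML configuration and resolves it against the packaged
#' defaults: any omitted key keeps its default, so an empty file yields the
#' default configuration. Recognized top-level keys: `mode`, `seed`,
#' `cv_max`, `slope_alpha`, `residual_threshold`, `washout_rate_per_min`,
#' `breath_palmitate_window`, `sampling_times_plasma`,
#' `sampling_times_breath`, and `protocols` (a list of records with the
#' [tracer_protocol()] fields). Unknown keys are validation errors that
#' name the offending key.
#'
#' @param path path to a YAML file, or a length-one character string of
#'   YAML text.
#' @return a validated [flux_config()].
#' @export
validate_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  if (is.null(raw)) raw <- list()
  known <- c("mode", "seed", "cv_max", "slope_alpha", "residual_threshold",
             "washout_rate_per_min", "breath_palmitate_window",
             "sampling_times_plasma", "sampling_times_breath", "protocols")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  protocols <- if (is.null(raw$protocols)) {
    default_protocols()
  } else {
    dplyr::bind_rows(lapply(raw$protocols, function(p) {
      do.call(tracer_protocol, p)
    }))
  }
  args <- raw[setdiff(names(raw), "protocols")]
  args$protocols <- protocols
  do.call(flux_config, args)
}
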