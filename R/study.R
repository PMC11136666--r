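# Study-level orchestration: raw tables in, per-animal flux results,
# tissue TCA contributions, group summary and QC log out.

#' Run the full tracer flux analysis on a study
#'
#' Takes the raw study tables — plasma GC-MS intensities, breath ion
#' currents (or delta-13C values), the animal/group table and optionally
#' tissue citrate intensities — and computes, per animal: glycerol Ra
#' (lipolysis), palmitate Ra/Rd, RaCO2 from bicarbonate dilution, the
#' bicarbonate-anchored palmitate oxidation rate, the fraction of
#' palmitate disappearance oxidized, and the fractional TCA contribution
#' of palmitate per tissue. Animals with missing baselines or too few
#' plateau points are flagged in the QC log and reported with `NA`s; the
#' study always continues.
#'
#' @param gcms long intensity table: `animal_id`, `analyte`,
#'   `timepoint_min`, `channel`, `intensity` (see [read_gcms_csv()]).
#' @param breath breath table: `animal_id`, `timepoint_min`, and either
#'   `i44`/`i45`/`i46` or `delta13c_permil` (see [read_breath_csv()]).
#' @param animals tibble with unique `animal_id` and optional `group`;
#'   derived from `gcms` when `NULL`.
#' @param tissue optional tissue citrate table: as `gcms` plus `tissue`.
#' @param config a [flux_config()].
#' @param irms_ref IRMS constants, see [irms_reference()].
#' @return object of class `"flux_study"` with elements `animals`
#'   (per-animal flux tibble incl. `qc_flags`), `tca` (per-tissue tibble),
#'   `plateaus`, `summary` (group mean +/- sem per quantity, with a Welch
#'   two-sample p-value when exactly two groups are present), `qc`
#'   (character log) and `config`.
#' @examples
#' sim <- simulate_flux_study(simulation_truth(n_animals = 2, seed = 7))
#' fit <- run_flux_study(sim$gcms, sim$breath, sim$animals, sim$tissue)
#' tidy(fit)
#' @export
run_flux_study <- function(gcms, breath, animals = NULL, tissue = NULL,
                           config = flux_config(),
                           irms_ref = irms_reference()) {
  stopifnot(inherits(config, "flux_config"))
  check_columns(gcms, c("animal_id", "analyte", "timepoint_min", "channel",
                        "intensity"), "GC-MS table")
  check_columns(breath, c("animal_id", "timepoint_min"), "breath table")
  qc <- character()
  note <- function(...) qc <<- c(qc, paste0(...))

  if (is.null(animals)) {
    animals <- tibble::tibble(animal_id = unique(gcms$animal_id))
  }
  check_columns(animals, "animal_id", "animal table")
  if (anyDuplicated(animals$animal_id)) {
    stop("duplicated animal_id rows in the animal table", call. = FALSE)
  }
  if (!"group" %in% names(animals)) animals$group <- "all"
  if (nrow(animals) == 0) {
    warning("empty animal set: returning an empty report", call. = FALSE)
    return(new_flux_study(
      animals = empty_flux_tibble(), tca = empty_tca_tibble(),
      plateaus = tibble::tibble(), summary = tibble::tibble(),
      qc = "empty animal set", config = config))
  }

  prot <- config$protocols
  bic <- prot[prot$analyte == "co2", ]
  palm <- prot[prot$analyte == "palmitate", ]
  glyc <- prot[prot$analyte == "glycerol", ]

  # --- plasma MIDs -> enrichment series -------------------------------
  mids <- correct_mids(gcms, config$panel,
                       residual_threshold = config$residual_threshold)
  plasma_series <- mids |>
    dplyr::group_by(.data$animal_id, .data$analyte) |>
    dplyr::group_modify(function(d, g) {
      frag <- config$panel[[g$analyte]]
      base <- d[d$timepoint_min == 0, ]
      if (nrow(base) == 0) {
        note("no t=0 baseline for ", g$animal_id, "/", g$analyte)
        return(tibble::tibble())
      }
      bvec <- base$fraction[order(base$mass_shift)]
      d |>
        dplyr::filter(.data$timepoint_min > 0) |>
        dplyr::group_by(.data$timepoint_min) |>
        dplyr::group_modify(function(dd, gg) {
          if (nrow(dd) == 0) return(tibble::tibble(enrichment = numeric()))
          if (any(dd$qc_warn)) {
            note("high MID residual: ", g$animal_id, "/", g$analyte,
                 " t=", gg$timepoint_min)
          }
          tibble::tibble(enrichment = enrichment_mpe(
            dd$fraction[order(dd$mass_shift)], bvec,
            frag$n_label_positions))
        }) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()

  plateau_for <- function(analyte_name, window) {
    s <- plasma_series[plasma_series$analyte == analyte_name, ]
    if (nrow(s) == 0) return(tibble::tibble())
    s |>
      dplyr::select("animal_id", "timepoint_min", "enrichment") |>
      safe_plateaus(window, config, note, analyte_name)
  }
  plat_palm <- plateau_for("palmitate",
                           c(palm$plateau_start_min, palm$plateau_end_min))
  plat_glyc <- plateau_for("glycerol",
                           c(glyc$plateau_start_min, glyc$plateau_end_min))

  # --- breath -> APE series -> plateaus -------------------------------
  if (all(c("i44", "i45", "i46") %in% names(breath))) {
    breath <- breath |>
      dplyr::mutate(delta13c_permil = delta13c_from_currents(
        .data$i44, .data$i45, .data$i46, irms_ref))
  } else if (!"delta13c_permil" %in% names(breath)) {
    stop("breath table needs i44/i45/i46 currents or delta13c_permil",
         call. = FALSE)
  }
  ape <- breath |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(d, g) {
      base <- d$delta13c_permil[d$timepoint_min == 0]
      if (length(base) == 0) {
        note("no t=0 breath baseline for ", g$animal_id)
        return(tibble::tibble())
      }
      d |>
        dplyr::filter(.data$timepoint_min > 0) |>
        dplyr::transmute(timepoint_min = .data$timepoint_min,
                         enrichment = ape_co2(.data$delta13c_permil,
                                              base[1], irms_ref$r13))
    }) |>
    dplyr::ungroup()

  plat_bic <- safe_plateaus(ape, c(bic$plateau_start_min,
                                   bic$plateau_end_min),
                            config, note, "breath co2 (bicarbonate)")
  ape_palm_phase <- ape
  if (!is.null(config$washout_rate_per_min) && nrow(plat_bic) > 0) {
    # subtract extrapolated mono-exponential bicarbonate 13CO2 washout
    k <- config$washout_rate_per_min
    t_end <- bic$infusion_end_min
    ape_palm_phase <- ape |>
      dplyr::left_join(plat_bic[, c("animal_id", "mean_enrichment")],
                       by = "animal_id") |>
      dplyr::mutate(enrichment = pmax(
        0, .data$enrichment - ifelse(
          .data$timepoint_min > t_end,
          .data$mean_enrichment * exp(-k * (.data$timepoint_min - t_end)),
          0))) |>
      dplyr::select(-"mean_enrichment")
  }
  plat_oxid <- safe_plateaus(ape_palm_phase, config$breath_palmitate_window,
                             config, note, "breath co2 (palmitate phase)")

  # --- per-animal fluxes ----------------------------------------------
  get_mean <- function(plat, id, flag) {
    r <- plat[plat$animal_id == id, , drop = FALSE]
    if (nrow(r) == 0 || !is.finite(r$mean_enrichment) ||
        r$mean_enrichment <= 0) {
      return(list(e = NA_real_, flag = paste0(flag, "_missing")))
    }
    list(e = r$mean_enrichment,
         flag = if (!r$steady) paste0(flag, "_unsteady") else character())
  }
  res <- purrr::map_dfr(seq_len(nrow(animals)), function(i) {
    id <- animals$animal_id[i]
    flags <- character()
    eg <- get_mean(plat_glyc, id, "glycerol_plateau")
    ep <- get_mean(plat_palm, id, "palmitate_plateau")
    eb <- get_mean(plat_bic, id, "bicarb_co2_plateau")
    eo <- get_mean(plat_oxid, id, "palm_co2_plateau")
    flags <- c(eg$flag, ep$flag, eb$flag, eo$flag)
    ra_g <- if (is.na(eg$e)) NA_real_ else
      ra_steady_state(glyc$rate_nmol_per_g_min, eg$e, config$mode)
    ra_p <- if (is.na(ep$e)) NA_real_ else
      ra_steady_state(palm$rate_nmol_per_g_min, ep$e, config$mode)
    raco2 <- if (is.na(eb$e)) NA_real_ else
      ra_co2(bic$rate_nmol_per_g_min, eb$e)
    rox <- if (anyNA(c(raco2, eo$e, ep$e))) NA_real_ else
      palmitate_oxidation(raco2, eo$e, ep$e, palm$label_atom_count)
    fox <- if (anyNA(c(rox, ra_p))) NA_real_ else
      withCallingHandlers(
        fraction_oxidized(rox, ra_p),
        warning = function(w) {
          flags <<- c(flags, "fraction_oxidized_gt_1")
          invokeRestart("muffleWarning")
        })
    tibble::tibble(
      animal_id = id, group = animals$group[i],
      e_glycerol = eg$e, e_palmitate = ep$e,
      eco2_bicarb = eb$e, eco2_palmitate = eo$e,
      ra_glycerol = ra_g, rd_glycerol = ra_g,
      ra_palmitate = ra_p, rd_palmitate = ra_p,
      ra_co2 = raco2, palmitate_oxidation = rox,
      fraction_oxidized = fox,
      qc_flags = paste(flags, collapse = ";"))
  })

  # --- tissue citrate --------------------------------------------------
  tca <- empty_tca_tibble()
  if (!is.null(tissue) && nrow(tissue) > 0) {
    check_columns(tissue, c("animal_id", "tissue", "analyte",
                            "timepoint_min", "channel", "intensity"),
                  "tissue table")
    tmids <- correct_mids(tissue, config$panel,
                          residual_threshold = config$residual_threshold)
    unlabeled <- c(1, numeric(config$panel$citrate$n_channels - 1L))
    tca <- tmids |>
      dplyr::group_by(.data$animal_id, .data$tissue) |>
      dplyr::group_modify(function(d, g) {
        tibble::tibble(total_citrate_enrichment = total_labeled_enrichment(
          d$fraction[order(d$mass_shift)], unlabeled))
      }) |>
      dplyr::ungroup() |>
      dplyr::left_join(res[, c("animal_id", "group", "e_palmitate")],
                       by = "animal_id") |>
      dplyr::mutate(fractional_contribution = ifelse(
        is.na(.data$e_palmitate), NA_real_,
        .data$total_citrate_enrichment / .data$e_palmitate)) |>
      dplyr::select("animal_id", "group", "tissue",
                    "total_citrate_enrichment", "fractional_contribution")
  }

  summary <- summarize_flux(res, tca)
  new_flux_study(animals = res, tca = tca,
                 plateaus = dplyr::bind_rows(
                   dplyr::mutate(plat_glyc, series = "glycerol"),
                   dplyr::mutate(plat_palm, series = "palmitate"),
                   dplyr::mutate(plat_bic, series = "co2_bicarb"),
                   dplyr::mutate(plat_oxid, series = "co2_palmitate")),
                 summary = summary, qc = qc, config = config)
}

safe_plateaus <- function(series, window, config, note, label) {
  if (nrow(series) == 0) return(tibble::tibble())
  series |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(d, g) {
      tryCatch(
        plateau_one(d$timepoint_min[d$timepoint_min >= window[1] &
                                      d$timepoint_min <= window[2]],
                    d$enrichment[d$timepoint_min >= window[1] &
                                   d$timepoint_min <= window[2]],
                    config$cv_max, config$slope_alpha),
        error = function(e) {
          note("plateau failed for ", g$animal_id, " [", label, "]: ",
               conditionMessage(e))
          tibble::tibble()
        })
    }) |>
    dplyr::ungroup()
}

flux_quantities <- c("ra_glycerol", "ra_palmitate", "ra_co2",
                     "palmitate_oxidation", "fraction_oxidized")

summarize_flux <- function(res, tca) {
  long <- res |>
    dplyr::select(dplyr::all_of(c("animal_id", "group", flux_quantities))) |>
    tidyr::pivot_longer(dplyr::all_of(flux_quantities),
                        names_to = "quantity", values_to = "value")
  if (nrow(tca) > 0) {
    long <- dplyr::bind_rows(long, tca |>
      dplyr::transmute(animal_id = .data$animal_id, group = .data$group,
                       quantity = paste0("tca_fraction_", .data$tissue),
                       value = .data$fractional_contribution))
  }
  out <- long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$quantity, .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sem(.data$value), .groups = "drop")
  grps <- unique(res$group)
  if (length(grps) == 2) {
    welch <- long |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::group_by(.data$quantity) |>
      dplyr::summarise(p_welch = tryCatch(
        stats::t.test(value ~ group, data = dplyr::pick(
          dplyr::everything()))$p.value,
        error = function(e) NA_real_), .groups = "drop")
    out <- dplyr::left_join(out, welch, by = "quantity")
  }
  out
}

empty_flux_tibble <- function() {
  tibble::tibble(animal_id = character(), group = character(),
                 e_glycerol = numeric(), e_palmitate = numeric(),
                 eco2_bicarb = numeric(), eco2_palmitate = numeric(),
                 ra_glycerol = numeric(), rd_glycerol = numeric(),
                 ra_palmitate = numeric(), rd_palmitate = numeric(),
                 ra_co2 = numeric(), palmitate_oxidation = numeric(),
                 fraction_oxidized = numeric(), qc_flags = character())
}

empty_tca_tibble <- function() {
  tibble::tibble(animal_id = character(), group = character(),
                 tissue = character(), total_citrate_enrichment = numeric(),
                 fractional_contribution = numeric())
}

new_flux_study <- function(animals, tca, plateaus, summary, qc, config) {
  structure(list(animals = animals, tca = tca, plateaus = plateaus,
                 summary = summary, qc = qc, config = config),
            class = "flux_study")
}

#' @export
print.flux_study <- function(x, ...) {
  cat("<flux_study>", nrow(x$animals), "animals,", x$config$mode,
      "Ra mode\n")
  if (nrow(x$summary)) print(x$summary)
  if (length(x$qc)) cat(length(x$qc), "QC note(s); see $qc\n")
  invisible(x)
}

#' Tidy per-animal results of a flux study
#'
#' One row per animal and quantity (rates in nmol g^-1 min^-1, fractions
#' dimensionless), broom-style.
#'
#' @param x a [run_flux_study()] result.
#' @param ... unused.
#' @return tibble with `animal_id`, `group`, `quantity`, `value`, `unit`,
#'   `qc_flags`.
#' @method tidy flux_study
#' @export
tidy.flux_study <- function(x, ...) {
  units <- c(ra_glycerol = "nmol/g/min", ra_palmitate = "nmol/g/min",
             ra_co2 = "nmol/g/min", palmitate_oxidation = "nmol/g/min",
             fraction_oxidized = "fraction")
  base <- x$animals |>
    dplyr::select(dplyr::all_of(c("animal_id", "group", flux_quantities,
                                  "qc_flags"))) |>
    tidyr::pivot_longer(dplyr::all_of(flux_quantities),
                        names_to = "quantity", values_to = "value") |>
    dplyr::mutate(unit = units[.data$quantity]) |>
    dplyr::select("animal_id", "group", "quantity", "value", "unit",
                  "qc_flags")
  if (nrow(x$tca) > 0) {
    base <- dplyr::bind_rows(base, x$tca |>
      dplyr::transmute(animal_id = .data$animal_id, group = .data$group,
                       quantity = paste0("tca_fraction_", .data$tissue),
                       value = .data$fractional_contribution,
                       unit = "fraction", qc_flags = ""))
  }
  base
}

#' One-row summary of a flux study
#'
#' @param x a [run_flux_study()] result.
#' @param ... unused.
#' @return tibble with `n_animals`, `n_groups`, `n_tissues`,
#'   `n_qc_notes`, `mode`.
#' @method glance flux_study
#' @export
glance.flux_study <- function(x, ...) {
  tibble::tibble(n_animals = nrow(x$animals),
                 n_groups = length(unique(x$animals$group)),
                 n_tissues = length(unique(x$tca$tissue)),
                 n_qc_notes = length(x$qc),
                 mode = x$config$mode)
}

#' Plot per-animal flux results by group
#'
#' @param object a [run_flux_study()] result.
#' @param ... unused.
#' @return a ggplot object: one facet per quantity, points per animal with
#'   group mean +/- sem.
#' @method autoplot flux_study
#' @export
autoplot.flux_study <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6, size = 1.5) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "pointrange",
                          colour = "firebrick", linewidth = 0.7) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot enrichment time courses
#'
#' @param series tibble with `timepoint_min`, `enrichment` and optional
#'   `animal_id` / `analyte` columns.
#' @return a ggplot object (enrichment shown as percent).
#' @export
plot_enrichment_series <- function(series) {
  check_columns(series, c("timepoint_min", "enrichment"),
                "enrichment series")
  mapping <- if ("animal_id" %in% names(series)) {
    ggplot2::aes(.data$timepoint_min, 100 * .data$enrichment,
                 group = .data$animal_id)
  } else {
    ggplot2::aes(.data$timepoint_min, 100 * .data$enrichment)
  }
  p <- ggplot2::ggplot(series, mapping) +
    ggplot2::geom_line(alpha = 0.6) + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (min)", y = "enrichment (MPE / APE, %)") +
    ggplot2::theme_minimal()
  if ("analyte" %in% names(series)) {
    p <- p + ggplot2::facet_wrap(~analyte, scales = "free_y")
  }
  p
}
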