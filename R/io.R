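# CSV readers with strict schema validation, and report writers.
# All tables are plain CSV with headers; timestamps are minutes from the
# start of the bicarbonate infusion (t = 0).

read_checked_csv <- function(path, spec, what, numeric_cols,
                             nonneg_cols = character()) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        progress = FALSE, col_types = readr::cols())
  miss <- setdiff(spec, names(df))
  if (length(miss)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cl in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad)) {
      stop(what, " file ", path, ", column '", cl, "': non-numeric value",
           " at data line ", bad[1] + 1L, call. = FALSE)
    }
    df[[cl]] <- v
  }
  for (cl in intersect(nonneg_cols, names(df))) {
    bad <- which(df[[cl]] < 0)
    if (length(bad)) {
      stop(what, " file ", path, ", column '", cl, "': negative value at",
           " data line ", bad[1] + 1L, call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Read a GC-MS intensity table
#'
#' Expected columns: `animal_id`, `analyte`, `timepoint_min`, `channel`
#' (0-based mass shift), `intensity`; an optional `tissue` column marks
#' tissue panels. Validation errors name the file, column and data line.
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_gcms_csv <- function(path) {
  read_checked_csv(path,
                   c("animal_id", "analyte", "timepoint_min", "channel",
                     "intensity"),
                   "GC-MS intensity",
                   numeric_cols = c("timepoint_min", "channel", "intensity"),
                   nonneg_cols = c("channel", "intensity"))
}

#' Read a breath IRMS table
#'
#' Expected columns: `animal_id`, `timepoint_min`, and either the ion
#' currents `i44`, `i45`, `i46` or a `delta13c_permil` column (exactly one
#' representation).
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_breath_csv <- function(path) {
  df <- read_checked_csv(path, c("animal_id", "timepoint_min"),
                         "breath",
                         numeric_cols = c("timepoint_min", "i44", "i45",
                                          "i46", "delta13c_permil"))
  has_currents <- all(c("i44", "i45", "i46") %in% names(df))
  has_delta <- "delta13c_permil" %in% names(df)
  if (has_currents == has_delta) {
    stop("breath file ", path, " must contain either i44/i45/i46 or ",
         "delta13c_permil (exactly one representation)", call. = FALSE)
  }
  if (has_currents) {
    bad <- which(df$i44 <= 0 | df$i45 < 0 | df$i46 < 0)
    if (length(bad)) {
      stop("breath file ", path, ": non-positive i44 or negative current",
           " at data line ", bad[1] + 1L, call. = FALSE)
    }
  }
  df
}

#' Read a metabolic-chamber export table
#'
#' Expected columns: `animal_id`, `timestamp_min`, `vo2`, `vco2`,
#' `x_total`, `light_cycle` (values `"light"`/`"dark"`, or logical/0-1
#' dark flags); optional `group`. The returned tibble carries a logical
#' `is_dark` column.
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_clams_csv <- function(path) {
  df <- read_checked_csv(path,
                         c("animal_id", "timestamp_min", "vo2", "vco2",
                           "x_total", "light_cycle"),
                         "calorimetry",
                         numeric_cols = c("timestamp_min", "vo2", "vco2",
                                          "x_total"),
                         nonneg_cols = c("vo2", "vco2", "x_total"))
  lc <- df$light_cycle
  df$is_dark <- if (is.character(lc)) {
    tolower(lc) %in% c("dark", "d", "true", "1")
  } else {
    as.logical(as.numeric(lc))
  }
  df$light_cycle <- NULL
  df
}

#' Write a flux study report to CSV
#'
#' One row per animal per quantity ([tidy()] layout), with a header echo
#' of the package version and Ra mode; the QC log is written next to it
#' as line-oriented text.
#'
#' @param x a [run_flux_study()] result.
#' @param path output CSV path; the QC log goes to `<path>.qc.txt`.
#' @param timestamp include a generation timestamp line (disable for
#'   byte-identical reports).
#' @return `path`, invisibly.
#' @export
write_flux_report <- function(x, path, timestamp = FALSE) {
  stopifnot(inherits(x, "flux_study"))
  header <- c(
    paste0("# fluxtrace ", as.character(utils::packageVersion("fluxtrace")),
           " flux report"),
    paste0("# mode: ", x$config$mode, "; seed: ", x$config$seed))
  if (timestamp) header <- c(header, paste0("# generated: ", Sys.time()))
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  readr::write_csv(tidy(x), path, append = TRUE, col_names = TRUE)
  writeLines(if (length(x$qc)) x$qc else "no QC notes",
             paste0(path, ".qc.txt"))
  invisible(path)
}

#' Write the simulated study tables to a directory
#'
#' Writes `gcms.csv`, `breath.csv`, `tissue.csv`, `animals.csv` and
#' `truth.csv` in exactly the schemas the readers consume.
#'
#' @param sim a [simulate_flux_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_csvs <- function(sim, dir) {
  stopifnot(inherits(sim, "flux_study_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$gcms, file.path(dir, "gcms.csv"))
  readr::write_csv(sim$breath, file.path(dir, "breath.csv"))
  readr::write_csv(sim$tissue, file.path(dir, "tissue.csv"))
  readr::write_csv(sim$animals, file.path(dir, "animals.csv"))
  readr::write_csv(sim$truth$animals, file.path(dir, "truth.csv"))
  invisible(dir)
}
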