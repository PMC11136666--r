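#' Natural isotope abundance table
#'
#' Heavy-isotope abundances used to build natural-abundance correction
#' matrices. Each element maps to a length-2 numeric vector giving the
#' probability that a single atom of that element carries a +1 or +2 mass
#' shift (e.g. for oxygen, 17O and 18O). Any value can be overridden, which
#' is how tracer-free "no spillover" matrices are obtained in tests and how
#' alternative literature abundance sets can be swapped in.
#'
#' Defaults: 13C 0.0107, 2H 0.000115, 15N 0.00364, 17O 0.00038,
#' 18O 0.00205, 29Si 0.04685, 30Si 0.03092, 33S 0.0075, 34S 0.0425.
#'
#' @param ... named overrides, e.g. `C = c(0, 0)` to zero carbon spillover.
#'   Each value must be a numeric vector of length 1 (the +1 shift; +2 is
#'   then 0) or 2, with entries in `[0, 1]`.
#' @return A named list of length-2 numeric vectors, one per element.
#' @examples
#' isotope_abundances()
#' isotope_abundances(C = c(0, 0), Si = c(0, 0))
#' @export
isotope_abundances <- function(...) {
  tab <- list(
    C  = c(0.0107, 0),
    H  = c(0.000115, 0),
    N  = c(0.00364, 0),
    O  = c(0.00038, 0.00205),
    Si = c(0.04685, 0.03092),
    S  = c(0.0075, 0.0425)
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots)))) {
      stop("abundance overrides must be named by element", call. = FALSE)
    }
    for (el in names(dots)) {
      v <- as.numeric(dots[[el]])
      if (length(v) == 1) v <- c(v, 0)
      if (length(v) != 2 || any(!is.finite(v)) || any(v < 0) || sum(v) > 1) {
        stop("invalid abundance for element '", el, "'", call. = FALSE)
      }
      tab[[el]] <- v
    }
  }
  tab
}

#' Define a monitored GC-MS fragment
#'
#' Describes one derivatized analyte fragment: its full elemental
#' composition (tracer backbone plus derivatization groups), how many
#' backbone atoms can carry tracer label, which element the label sits on,
#' the m/z of the M+0 channel, and how many mass channels are monitored.
#'
#' @param analyte analyte name, e.g. `"citrate"`.
#' @param elements named integer vector of atom counts for the full
#'   fragment, e.g. `c(C = 21, H = 39, O = 7, Si = 2)`.
#' @param base_mz integer m/z of the M+0 channel (must be > 0).
#' @param n_channels number of monitored channels M+0..M+(n_channels - 1).
#' @param n_label_positions number of backbone atoms that can carry label.
#' @param label_element element carrying the tracer label, `"C"` for 13C
#'   tracers or `"H"` for deuterated tracers.
#' @return An object of class `"fragment"` (a validated list).
#' @examples
#' fragment("citrate", c(C = 21, H = 39, O = 7, Si = 2),
#'          base_mz = 459, n_channels = 7, n_label_positions = 6)
#' @export
fragment <- function(analyte, elements, base_mz, n_channels,
                     n_label_positions, label_element = "C") {
  stopifnot(is.character(analyte), length(analyte) == 1, nzchar(analyte))
  elements <- unlist(elements)
  if (is.null(names(elements)) || any(!nzchar(names(elements)))) {
    stop("'elements' must be a named vector of atom counts", call. = FALSE)
  }
  elements <- vapply(elements, as.integer, integer(1))
  if (any(elements < 0)) stop("atom counts must be >= 0", call. = FALSE)
  if (!is.numeric(base_mz) || base_mz <= 0) {
    stop("'base_mz' must be a positive m/z", call. = FALSE)
  }
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1) {
    stop("'n_channels' must be >= 1", call. = FALSE)
  }
  n_label_positions <- as.integer(n_label_positions)
  if (!label_element %in% names(elements)) {
    stop("label element '", label_element, "' absent from composition",
         call. = FALSE)
  }
  if (n_label_positions < 0 || n_label_positions > elements[[label_element]]) {
    stop("'n_label_positions' exceeds available ", label_element, " atoms",
         call. = FALSE)
  }
  structure(
    list(analyte = analyte, elements = elements,
         base_mz = as.integer(base_mz), n_channels = n_channels,
         n_label_positions = n_label_positions,
         label_element = label_element),
    class = "fragment"
  )
}

#' @export
print.fragment <- function(x, ...) {
  comp <- paste0(names(x$elements), x$elements, collapse = "")
  cat(sprintf(
    "<fragment> %s [%s], m/z %d, M+0..M+%d, %d labelable %s\n",
    x$analyte, comp, x$base_mz, x$n_channels - 1L,
    x$n_label_positions, x$label_element), ...)
  invisible(x)
}

#' Default fragment panel for the infusion protocol
#'
#' The three fragments monitored in the tracer study, as TBDMS-derived
#' GC-MS fragments:
#' \describe{
#'   \item{citrate}{m/z 459-465 (M+0..M+6), 6 labelable backbone carbons.}
#'   \item{palmitate}{\[M-57\] fragment at m/z 313, channels M+0..M+16,
#'     16 labelable carbons (uniformly 13C-labelled tracer appears at M+16).}
#'   \item{glycerol}{\[M-57\] fragment at m/z 377, channels M+0..M+5,
#'     label element H (the d5 tracer appears at M+5).}
#' }
#' Elemental formulas are packaged defaults for the correction matrices and
#' can be replaced with [fragment()] if a different derivative is used.
#'
#' @return Named list of [fragment()] objects.
#' @export
default_fragment_panel <- function() {
  list(
    citrate = fragment(
      "citrate", c(C = 21, H = 39, O = 7, Si = 2),
      base_mz = 459, n_channels = 7, n_label_positions = 6),
    palmitate = fragment(
      "palmitate", c(C = 18, H = 37, O = 2, Si = 1),
      base_mz = 313, n_channels = 17, n_label_positions = 16),
    glycerol = fragment(
      "glycerol", c(C = 17, H = 41, O = 3, Si = 3),
      base_mz = 377, n_channels = 6, n_label_positions = 5,
      label_element = "H")
  )
}
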