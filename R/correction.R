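# Natural-abundance correction of mass-isotopomer distributions.
# Column j of the correction matrix is the distribution of mass shifts that
# natural heavy isotopes add to a molecule already carrying j tracer labels;
# the j label-occupied backbone positions are excluded from the convolution
# so tracer atoms are not double counted.

# distribution of total mass shift for n atoms of one element,
# each shifting +1 w.p. p[1], +2 w.p. p[2]; truncated to max_len terms
atom_shift_dist <- function(n, p, max_len) {
  one <- c(1 - p[1] - p[2], p[1], p[2])
  out <- 1
  for (i in seq_len(n)) {
    out <- poly_mult_trunc(out, one, max_len)
  }
  out
}

poly_mult_trunc <- function(a, b, max_len) {
  out <- numeric(min(length(a) + length(b) - 1L, max_len))
  for (i in seq_along(a)) {
    jmax <- min(length(b), max_len - i + 1L)
    if (jmax < 1) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Build a natural-abundance correction matrix
#'
#' Computes the lower-triangular matrix `M` such that a measured (uncorrected)
#' mass-isotopomer distribution is `M %*% x`, where `x` is the tracer-only
#' distribution. Entry `M[i, j]` is the probability that natural heavy
#' isotopes add a mass shift of `i - j` to a molecule carrying `j - 1`
#' tracer labels, obtained by multinomial convolution over every atom of the
#' fragment except the label-occupied backbone positions. Rows beyond the
#' monitored channel range are truncated, so columns sum to at most 1 and to
#' 1 exactly when the channel range covers all achievable shifts.
#'
#' @param frag a [fragment()].
#' @param abundances heavy-isotope table from [isotope_abundances()].
#' @return `n_channels x n_channels` numeric matrix with attributes
#'   `analyte` and `abundances`.
#' @examples
#' cm <- na_correction_matrix(default_fragment_panel()$citrate)
#' colSums(cm)
#' @export
na_correction_matrix <- function(frag, abundances = isotope_abundances()) {
  stopifnot(inherits(frag, "fragment"))
  missing_el <- setdiff(names(frag$elements), names(abundances))
  if (length(missing_el)) {
    stop("no natural abundance defined for element(s): ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  n <- frag$n_channels
  M <- matrix(0, n, n)
  for (j in seq_len(n) - 1L) {
    counts <- frag$elements
    # label-occupied positions cannot also be natural heavy isotopes
    excl <- min(j, frag$n_label_positions)
    counts[frag$label_element] <- counts[frag$label_element] - excl
    d <- 1
    for (el in names(counts)) {
      if (counts[[el]] > 0) {
        d <- poly_mult_trunc(d, atom_shift_dist(counts[[el]],
                                                abundances[[el]], n - j),
                             n - j)
      }
    }
    M[(j + 1L):n, j + 1L] <- c(d, numeric(n - j - length(d)))
  }
  attr(M, "analyte") <- frag$analyte
  attr(M, "abundances") <- abundances
  M
}

#' Correct one measured intensity vector to a mass-isotopomer distribution
#'
#' Solves the non-negative least-squares problem
#' `min || M x - y ||` with `x >= 0`, where `y` is the measured intensity
#' vector normalized to sum 1, then renormalizes `x` to sum 1. NNLS is used
#' instead of a plain matrix inverse because measurement noise can otherwise
#' produce unphysical negative fractions. The residual norm is kept as a QC
#' metric; residuals above `residual_threshold` set a warning flag without
#' failing the sample.
#'
#' @param intensities non-negative numeric vector, one value per monitored
#'   channel M+0..M+k; at least one must be positive.
#' @param cmat correction matrix from [na_correction_matrix()].
#' @param residual_threshold residual norm above which `qc_warn` is set.
#' @return list with `fractions` (sums to 1), `residual_norm`, `qc_warn`.
#' @examples
#' frag <- default_fragment_panel()$citrate
#' cm <- na_correction_matrix(frag)
#' correct_mid(as.vector(cm %*% c(0.9, 0, 0.1, 0, 0, 0, 0)), cm)$fractions
#' @export
correct_mid <- function(intensities, cmat, residual_threshold = 0.05) {
  intensities <- as.numeric(intensities)
  if (length(intensities) != nrow(cmat)) {
    stop("intensity vector length (", length(intensities),
         ") does not match correction matrix size (", nrow(cmat), ")",
         call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  tot <- sum(intensities)
  if (tot <= 0) stop("all-zero intensity vector", call. = FALSE)
  y <- intensities / tot
  x <- pracma::lsqnonneg(cmat, y)$x
  resid <- sqrt(sum((cmat %*% x - y)^2))
  s <- sum(x)
  if (s <= 0) stop("degenerate NNLS solution (all-zero fractions)",
                   call. = FALSE)
  list(fractions = x / s,
       residual_norm = resid,
       qc_warn = resid > residual_threshold)
}

#' Correct a table of GC-MS intensities to mass-isotopomer distributions
#'
#' Data-frame front end to [correct_mid()]: takes the long intensity table
#' produced by [read_gcms_csv()] or [simulate_flux_study()] (one row per
#' channel), groups by sample, and returns one row per corrected mass
#' isotopomer.
#'
#' @param intensities tibble with columns `animal_id`, `analyte`,
#'   `timepoint_min`, `channel` (0-based mass shift), `intensity`, and
#'   optionally `tissue`.
#' @param panel named list of [fragment()]s covering every analyte present.
#' @param abundances see [isotope_abundances()].
#' @param residual_threshold per-sample NNLS residual QC threshold.
#' @return tibble with columns `animal_id`, (`tissue`,) `analyte`,
#'   `timepoint_min`, `mass_shift`, `fraction`, `residual_norm`, `qc_warn`.
#' @export
correct_mids <- function(intensities, panel = default_fragment_panel(),
                         abundances = isotope_abundances(),
                         residual_threshold = 0.05) {
  req <- c("animal_id", "analyte", "timepoint_min", "channel", "intensity")
  check_columns(intensities, req, "intensity table")
  unknown <- setdiff(unique(intensities$analyte), names(panel))
  if (length(unknown)) {
    stop("analyte(s) not in fragment panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mats <- lapply(panel, na_correction_matrix, abundances = abundances)
  keys <- intersect(c("animal_id", "tissue", "analyte", "timepoint_min"),
                    names(intensities))
  intensities |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$channel, .by_group = TRUE) |>
    dplyr::group_modify(function(d, g) {
      frag <- panel[[g$analyte]]
      if (!identical(as.integer(d$channel),
                     seq_len(frag$n_channels) - 1L)) {
        stop("analyte '", g$analyte, "' needs channels 0..",
             frag$n_channels - 1L, " exactly once per sample", call. = FALSE)
      }
      res <- correct_mid(d$intensity, mats[[g$analyte]],
                         residual_threshold = residual_threshold)
      tibble::tibble(mass_shift = seq_along(res$fractions) - 1L,
                     fraction = res$fractions,
                     residual_norm = res$residual_norm,
                     qc_warn = res$qc_warn)
    }) |>
    dplyr::ungroup()
}
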