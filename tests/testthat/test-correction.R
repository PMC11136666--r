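# natural-abundance correction matrices and MID inversion

test_that("correction matrix is identity when no heavy isotopes exist", {
  for (frag in default_fragment_panel()) {
    cm <- na_correction_matrix(frag, null_abundances())
    expect_equal(cm, diag(frag$n_channels), ignore_attr = TRUE)
  }
})

test_that("two-carbon fragment matches the hand binomial convolution", {
  frag <- toy_fragment()
  cm <- na_correction_matrix(frag, isotope_abundances(
    C = 0.0107, H = 0, N = 0, O = c(0, 0), Si = c(0, 0), S = c(0, 0)))
  # column 0: both carbons available, truncated to shifts {0, 1}
  expect_equal(cm[, 1], c(0.9893^2, 2 * 0.9893 * 0.0107), tolerance = 1e-12)
  # column 1: the labelled backbone carbon is excluded, one C remains
  expect_equal(cm[, 2], c(0, 0.9893), tolerance = 1e-12)
})

test_that("matrices are lower-triangular, non-negative, column sums <= 1", {
  for (frag in default_fragment_panel()) {
    cm <- na_correction_matrix(frag)
    expect_true(all(cm >= 0))
    expect_true(all(cm[upper.tri(cm)] == 0))
    expect_true(all(colSums(cm) <= 1 + 1e-12))
  }
})

test_that("columns sum to 1 when the channel range covers all shifts", {
  # toy fragment with generous channel range: 2 C, max shift 2 (no +2
  # isotope for C), so 4 channels cover everything
  frag <- fragment("toy", c(C = 2), base_mz = 100, n_channels = 4,
                   n_label_positions = 1)
  cm <- na_correction_matrix(frag, isotope_abundances(
    C = 0.0107, H = 0, N = 0, O = c(0, 0), Si = c(0, 0), S = c(0, 0)))
  expect_equal(colSums(cm)[1:3], rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("deuterium-labelled fragments exclude H atoms per label", {
  frag <- default_fragment_panel()$glycerol
  abund <- isotope_abundances(C = 0, N = 0, O = c(0, 0), Si = c(0, 0),
                              S = c(0, 0))  # only 2H active
  cm <- na_correction_matrix(frag, abund)
  p <- isotope_abundances()$H[1]
  nH <- frag$elements[["H"]]
  expect_equal(cm[1, 1], (1 - p)^nH, tolerance = 1e-12)
  expect_equal(cm[3, 3], (1 - p)^(nH - 2), tolerance = 1e-12)
})

test_that("correct_mid on an identity matrix only renormalizes", {
  res <- correct_mid(c(3, 1), diag(2))
  expect_equal(res$fractions, c(0.75, 0.25))
  expect_equal(res$residual_norm, 0)
  expect_false(res$qc_warn)
})

test_that("forward-convolve then correct is the identity at zero noise", {
  cm <- na_correction_matrix(default_fragment_panel()$citrate)
  set.seed(42)
  for (i in 1:25) {
    x <- random_mid(7)
    res <- correct_mid(as.vector(cm %*% x), cm)
    expect_lt(max(abs(res$fractions - x)), 1e-9)
  }
})

test_that("a pure unlabelled analyte corrects to (1, 0, ..., 0)", {
  cm <- na_correction_matrix(default_fragment_panel()$citrate)
  res <- correct_mid(cm[, 1], cm)
  expect_equal(res$fractions, c(1, rep(0, 6)), tolerance = 1e-9)
})

test_that("correct_mid guards degenerate input and flags big residuals", {
  cm <- na_correction_matrix(default_fragment_panel()$citrate)
  expect_error(correct_mid(rep(0, 7), cm), "all-zero")
  expect_error(correct_mid(rep(1, 6), cm), "does not match")
  # an intensity pattern no non-negative MID can produce well
  res <- correct_mid(c(0, 1, 0, 1, 0, 1, 0), cm)
  expect_true(res$qc_warn)
})

test_that("unknown elements in a composition are configuration errors", {
  frag <- fragment("odd", c(C = 2, P = 1), base_mz = 50, n_channels = 2,
                   n_label_positions = 1)
  expect_error(na_correction_matrix(frag), "P")
})

test_that("correct_mids handles grouped long tables with QC columns", {
  frag <- default_fragment_panel()$citrate
  cm <- na_correction_matrix(frag)
  x <- c(0.9, 0, 0.05, 0, 0.03, 0, 0.02)
  tab <- tidyr::crossing(animal_id = c("a", "b"), timepoint_min = c(0, 180)) |>
    dplyr::cross_join(tibble::tibble(channel = 0:6)) |>
    dplyr::mutate(analyte = "citrate",
                  intensity = rep(as.vector(cm %*% x) * 1e6, 4))
  out <- correct_mids(tab)
  expect_equal(nrow(out), 4 * 7)
  expect_equal(out$fraction[out$animal_id == "a" &
                              out$timepoint_min == 0],
               x, tolerance = 1e-9)
  expect_false(any(out$qc_warn))
  # missing channel is an error naming the analyte
  expect_error(correct_mids(tab[tab$channel != 3, ]), "citrate")
})
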