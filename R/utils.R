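#' @importFrom rlang .data
#' @importFrom stats rnorm rpois sd t.test lm coef
NULL

check_columns <- function(df, required, what) {
  if (!is.data.frame(df)) stop(what, " must be a data frame", call. = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
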