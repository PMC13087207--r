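#' Standardize age to mean 0, SD 1
#'
#' Mean-centres and scales age to standard deviation units using the pooled
#' mean and sample SD (n - 1 denominator) over all records of both
#' populations, adding a column `x` and recording the scaling so curves can
#' be back-transformed to years.
#'
#' @param records A breeding-record tibble.
#' @param scaling Optional list with `mean` and `sd` (years): use these
#'   constants instead of the empirical pooled values, e.g. the generator's
#'   own constants so that generator and model share one x-axis.
#' @return A list with `records` (input plus `x` column) and `scaling`
#'   (list with `mean`, `sd`).
#' @export
standardize_age <- function(records, scaling = NULL) {
  if (!nrow(records)) abort("standardize_age: empty table")
  if (is.null(scaling)) {
    m <- mean(records$age)
    s <- sd(records$age)
    if (!is.finite(s) || s == 0) {
      abort("standardize_age: zero age variance; cannot standardize")
    }
    scaling <- list(mean = m, sd = s)
  }
  if (scaling$sd <= 0) abort("standardize_age: scaling sd must be > 0")
  records$x <- (records$age - scaling$mean) / scaling$sd
  list(records = records, scaling = scaling)
}

#' Back-transform standardized age to years
#'
#' @param x Standardized age value(s).
#' @param scaling A list with `mean` and `sd` in years.
#' @return Age in years.
#' @export
unstandardize_age <- function(x, scaling) scaling$mean + scaling$sd * x
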