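# Small descriptive-statistics helpers used for internal-consistency checks
# of published cohort summaries. Group-comparison machinery (t-tests, ICC)
# is deliberately not part of the pipeline; these are test utilities.

#' Coefficient of variation in percent
#'
#' `100 * sd / mean`, the form in which cohort variability of VT and DVR is
#' conventionally reported.
#'
#' @param mean,sd Summary statistics (mean > 0).
#' @return CV in percent.
#' @examples
#' cv_percent(3.20, 0.47)
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean <= 0)) stop("mean must be > 0 for a CV")
  100 * sd / mean
}
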