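#' Chi-square goodness-of-fit test for a segregation ratio
#'
#' Tests observed phenotype-class counts in an F2 (or other) population
#' against an expected Mendelian ratio. With the Yates continuity
#' correction (the default for two classes) each deviation is shrunk by
#' 0.5 and clamped at zero before squaring:
#' `sum(max(|O - E| - c, 0)^2 / E)` with `c = 0.5`. A 29:91 segregation
#' against 1:3 gives 0.011 with the correction and 0.044 without.
#'
#' @param observed vector of class counts (>= 0, total > 0).
#' @param expected_ratio vector of positive ratio terms, same length
#'   (e.g. `c(1, 3)`).
#' @param yates apply the continuity correction; defaults to TRUE for
#'   two-class tests and FALSE otherwise.
#' @param labels optional class names.
#' @return list with `statistic`, `df`, `p_value`, `expected` and
#'   `observed`; a warning is emitted when any expected count is below 5.
#' @examples
#' chi_square_segregation(c(29, 91), c(1, 3))$statistic  # 0.0111
#' @export
chi_square_segregation <- function(observed, expected_ratio,
                                   yates = length(observed) == 2,
                                   labels = NULL) {
  if (length(observed) != length(expected_ratio)) {
    stop_param("observed and expected_ratio must have the same length")
  }
  if (any(observed < 0)) stop_param("counts must be >= 0")
  if (any(expected_ratio <= 0)) stop_param("ratio entries must be > 0")
  total <- sum(observed)
  if (total <= 0) stop_param("total observed count must be > 0")
  expected <- total * expected_ratio / sum(expected_ratio)
  if (any(expected == 0)) stop_param("expected counts must be nonzero")
  if (any(expected < 5)) {
    warning("some expected counts are below 5; the chi-square approximation may be poor")
  }
  correction <- if (isTRUE(yates)) 0.5 else 0
  dev <- pmax(abs(observed - expected) - correction, 0)
  statistic <- sum(dev^2 / expected)
  df <- length(observed) - 1
  list(statistic = statistic, df = df,
       p_value = pchisq(statistic, df, lower.tail = FALSE),
       expected = expected,
       observed = setNames(observed, labels))
}
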