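# Marital-status weighting of routine-and-manual smoking prevalence.

#' Marital-status prevalence weight
#'
#' The ratio of smoking prevalence in a marital-status group to prevalence
#' in the general adult population, e.g. 27/20 = 1.35 for single adults.
#'
#' @param general General adult prevalence (%), > 0.
#' @param marital Prevalence in the marital-status group (%), >= 0.
#' @return Dimensionless weight.
#' @examples
#' marital_weight(20, 27)  # 1.35
#' marital_weight(20, 14)  # 0.70
#' @export
marital_weight <- function(general, marital) {
  if (!is.numeric(general) || general <= 0)
    stop("general prevalence must be > 0", call. = FALSE)
  if (any(marital < 0)) stop("marital prevalence must be >= 0", call. = FALSE)
  marital / general
}

#' Sex-by-marital-status smoking prevalence
#'
#' Multiplies the routine-and-manual base prevalence for each sex by the
#' marital-status weight for each group, giving the six smoking rates used
#' throughout the pipeline (e.g. single man 33 x 1.35 = 44.55%, printed
#' 44.6). Rates are carried unrounded and capped at 100.
#'
#' The marital-status prevalences are not sex-specific in the source survey;
#' the multiplicative weighting is an approximation, not an estimated joint
#' distribution.
#'
#' @param base_prevalence Named vector, `% by sex` (`male`, `female`).
#' @param general_prevalence General adult prevalence (%), > 0.
#' @param marital_prevalence Named vector, `%` for `single`, `married`,
#'   `cohabiting`.
#' @return An object of class `prevalence_set`: list with the inputs, the
#'   `weights` by marital status, and `rates`, a sex x marital-status matrix
#'   of percentages.
#' @examples
#' ps <- weighted_prevalence()
#' ps$rates["male", "single"]   # 44.55
#' @export
weighted_prevalence <- function(base_prevalence = c(male = 33, female = 32),
                                general_prevalence = 20,
                                marital_prevalence = c(single = 27, married = 14,
                                                       cohabiting = 33)) {
  if (any(base_prevalence < 0 | base_prevalence > 100) ||
      any(marital_prevalence < 0 | marital_prevalence > 100))
    stop("prevalences must lie in [0, 100]", call. = FALSE)
  w <- marital_weight(general_prevalence, marital_prevalence)
  rates <- outer(base_prevalence[c("male", "female")], w)
  rates <- pmin(rates, 100)
  dimnames(rates) <- list(c("male", "female"), names(marital_prevalence))
  structure(list(base = base_prevalence,
                 general = general_prevalence,
                 by_marital = marital_prevalence,
                 weights = w,
                 rates = rates),
            class = "prevalence_set")
}

#' @export
print.prevalence_set <- function(x, ...) {
  cat("Smoking prevalence (%), base rates weighted by marital status\n")
  print(round_half_up(x$rates, 1))
  invisible(x)
}

#' Expected number of smoking parents per couple
#'
#' For a two-parent household of the given marital status, the expected
#' number of smoking adults: the sum of the male and female weighted rates
#' (as fractions). This is a sum of marginal probabilities, not the
#' probability of "at least one smoker" -- it double-counts two-smoker homes,
#' which the sole-smoker split later resolves. It may exceed 1 (cohabiting
#' couples: 0.5445 + 0.528 = 1.0725), a property of the marginal-sum
#' approximation at the heart of the method.
#'
#' @param ps A [weighted_prevalence()] object.
#' @param marital `"married"` or `"cohabiting"`.
#' @return Expected smoking parents per couple (dimensionless, >= 0).
#' @examples
#' couple_smoking_rate(weighted_prevalence(), "married")     # 0.455
#' couple_smoking_rate(weighted_prevalence(), "cohabiting")  # 1.0725
#' @export
couple_smoking_rate <- function(ps, marital = c("married", "cohabiting")) {
  marital <- match.arg(marital)
  sum(ps$rates[, marital]) / 100
}
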