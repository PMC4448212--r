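# Modified OECD income equivalisation and poverty thresholds.

#' Modified OECD equivalence scale
#'
#' The equivalence weights used by Households Below Average Income (HBAI)
#' statistics, rescaled so that a childless adult couple has factor 1.00:
#' first adult 0.67, each additional person aged 14 or over 0.33, each child
#' under 14 0.20.
#'
#' @param first_adult,additional_14plus,child_under14 Positive weights.
#' @return An object of class `oecd_scale` (named numeric vector).
#' @examples
#' oecd_scale()
#' @export
oecd_scale <- function(first_adult = 0.67, additional_14plus = 0.33,
                       child_under14 = 0.20) {
  w <- c(first_adult = first_adult, additional_14plus = additional_14plus,
         child_under14 = child_under14)
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0))
    stop("equivalence weights must be positive", call. = FALSE)
  structure(w, class = "oecd_scale")
}

#' Household composition
#'
#' A household is described by its adult count (1 or 2) and its children,
#' split by whether they are under 14 (the age at which the modified OECD
#' scale switches a child to the adult weight).
#'
#' @param n_adults 1 or 2.
#' @param n_children_under14,n_children_14plus Non-negative integer counts.
#' @return An object of class `household_composition`.
#' @examples
#' household_composition(1, n_children_under14 = 1)  # single parent, one child
#' @export
household_composition <- function(n_adults, n_children_under14 = 0,
                                  n_children_14plus = 0) {
  if (!n_adults %in% c(1, 2))
    stop("n_adults must be 1 or 2", call. = FALSE)
  if (n_children_under14 < 0 || n_children_14plus < 0 ||
      n_children_under14 != round(n_children_under14) ||
      n_children_14plus != round(n_children_14plus))
    stop("child counts must be non-negative integers", call. = FALSE)
  structure(list(n_adults = n_adults,
                 n_children_under14 = n_children_under14,
                 n_children_14plus = n_children_14plus),
            class = "household_composition")
}

#' Equivalence factor for a household
#'
#' Computes the modified OECD factor: `first_adult` for the first adult,
#' `additional_14plus` for the second adult and each child aged 14 or over,
#' `child_under14` for each younger child. A childless couple has factor
#' 1.00 by construction (0.67 + 0.33), the scale's reference point.
#'
#' @param comp A [household_composition()].
#' @param scale An [oecd_scale()].
#' @return Dimensionless positive factor.
#' @examples
#' equivalence_factor(household_composition(2))            # 1.00
#' equivalence_factor(household_composition(1, 1))         # 0.87
#' equivalence_factor(household_composition(2, 1, 1))      # 1.53
#' @export
equivalence_factor <- function(comp, scale = oecd_scale()) {
  if (!inherits(comp, "household_composition"))
    comp <- do.call(household_composition, as.list(comp))
  unname(scale[["first_adult"]] +
    scale[["additional_14plus"]] * (comp$n_adults - 1 + comp$n_children_14plus) +
    scale[["child_under14"]] * comp$n_children_under14)
}

#' Equivalised income threshold
#'
#' A band edge on the equivalised income scale: `fraction` times the median
#' equivalised household income. With the defaults this is the relative
#' poverty line, 0.60 x 427 = 256.2 GBP/week (reported as GBP 256).
#'
#' @param median Median equivalised income, GBP/week, > 0.
#' @param fraction Fraction of the median in (0, 1].
#' @return Equivalised GBP/week, unrounded.
#' @examples
#' income_threshold(427, 0.60)   # 256.2
#' @export
income_threshold <- function(median, fraction) {
  if (!is.numeric(median) || median <= 0)
    stop("median income must be positive", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  median * fraction
}

#' Household-level (unequivalised) income threshold
#'
#' Converts an equivalised band edge back to the actual weekly income a
#' specific household needs to sit at that edge: the equivalised threshold
#' times the household's equivalence factor. For a single parent with one
#' child under 14 the 60% line is 0.87 x 256.2 = 222.9 (GBP 223); for a
#' couple with one child under 14 and one aged 14+ it is 1.53 x 256.2 =
#' 392.0.
#'
#' @inheritParams income_threshold
#' @inheritParams equivalence_factor
#' @return Unequivalised GBP/week, unrounded.
#' @examples
#' household_threshold(427, 0.6, household_composition(1, 1))     # 222.9
#' household_threshold(427, 0.6, household_composition(2, 1, 1))  # 392.0
#' @export
household_threshold <- function(median, fraction, comp, scale = oecd_scale()) {
  income_threshold(median, fraction) * equivalence_factor(comp, scale)
}
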