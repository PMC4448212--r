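# Children drawn into effective poverty by parental tobacco expenditure.

#' Children drawn into poverty when tobacco spend is subtracted from income
#'
#' Applies the half/all rule to the between-band (60-70% of median)
#' attribution table: all children in two-smoker households, and half of the
#' children living with exactly one smoking parent (single parents or
#' couples with one smoker), are counted as drawn into effective poverty.
#' Fractions are applied to the unrounded configuration row totals.
#'
#' The rule rests on two observations: the income width of the 60-70% band
#' for typical family structures is comparable to the weekly spend of two
#' smokers (see [band_width_diagnostic()]), and the population is spread
#' fairly evenly inside the band, so a spend of about half the band width
#' pushes about half of the one-smoker households under the line.
#'
#' @param between_band An [attribution_table()] built from the 60-70% band.
#' @param fractions Named fractions `one_smoker` and `two_smoker` in
#'   \[0, 1\] (defaults 0.5 and 1.0).
#' @return An object of class `drawn_in`: list with `with_smoker` (the input
#'   table), `with_smoker_by_config`, `drawn_in_by_config`,
#'   `total_with_smoker`, `total_drawn_in` (thousands, unrounded) and the
#'   `fractions` used.
#' @examples
#' inp <- study_inputs()
#' between <- between_band_table(children_table(inp, "below_upper"),
#'                               children_table(inp, "poverty"))
#' di <- drawn_in_counts(attribution_table(between, weighted_prevalence()))
#' di$total_drawn_in  # about 432.3 thousand
#' @export
drawn_in_counts <- function(between_band,
                            fractions = c(one_smoker = 0.5, two_smoker = 1.0)) {
  if (any(fractions < 0 | fractions > 1))
    stop("drawn-in fractions must lie in [0, 1]", call. = FALSE)
  row_totals <- rowSums(between_band)
  frac <- ifelse(grepl("both_smoke$", names(row_totals)),
                 fractions[["two_smoker"]], fractions[["one_smoker"]])
  drawn <- row_totals * frac
  structure(list(with_smoker = between_band,
                 with_smoker_by_config = row_totals,
                 drawn_in_by_config = drawn,
                 total_with_smoker = sum(row_totals),
                 total_drawn_in = sum(drawn),
                 fractions = fractions),
            class = "drawn_in")
}

#' @export
print.drawn_in <- function(x, ...) {
  cat("Children drawn into effective poverty (thousands)\n")
  m <- cbind(with_smoker = x$with_smoker_by_config,
             drawn_in = x$drawn_in_by_config)
  m <- rbind(m, total = c(x$total_with_smoker, x$total_drawn_in))
  print(round(m))
  invisible(x)
}

#' @export
as.data.frame.drawn_in <- function(x, ...) {
  d <- as.data.frame(x$with_smoker)
  wide <- stats::reshape(d, idvar = "configuration", timevar = "family_size",
                         direction = "wide")
  names(wide) <- sub("children_thousands.", "children_", names(wide), fixed = TRUE)
  wide$total_with_smoker <- unname(x$with_smoker_by_config[wide$configuration])
  wide$drawn_in <- unname(x$drawn_in_by_config[wide$configuration])
  rownames(wide) <- NULL
  wide
}

#' Band-width diagnostic for the half/all rule
#'
#' For each household composition, compares the unequivalised income width
#' of the 60-70% band (`0.1 x median x equivalence factor`) against average
#' weekly tobacco spend: flags whether two-smoker spend covers the full
#' width and one-smoker spend covers half of it. One-smoker spend is the
#' mean of the male and female overall averages; two-smoker spend their sum.
#'
#' @param inputs A [study_inputs()] object.
#' @param compositions Named list of [household_composition()] objects;
#'   defaults to a single parent with one young child and a couple with two
#'   children (one aged 14+).
#' @return A data frame with the factor, band width, spends and flags per
#'   composition.
#' @export
band_width_diagnostic <- function(inputs = study_inputs(),
                                  compositions = list(
                                    single_1child = household_composition(1, 1),
                                    couple_2children = household_composition(2, 1, 1))) {
  scale <- do.call(oecd_scale, as.list(inputs$equivalence_scale))
  ep <- expenditure_profile(inputs)
  one <- mean(c(ep$female$average, ep$male$average))
  two <- ep$female$average + ep$male$average
  rows <- lapply(names(compositions), function(nm) {
    comp <- compositions[[nm]]
    f <- equivalence_factor(comp, scale)
    width <- household_threshold(inputs$median_income, inputs$upper_band_fraction,
                                 comp, scale) -
             household_threshold(inputs$median_income, inputs$poverty_fraction,
                                 comp, scale)
    data.frame(composition = nm, factor = f, band_width_gbp = width,
               one_smoker_spend_gbp = one, two_smoker_spend_gbp = two,
               two_smoker_covers_width = two >= width,
               one_smoker_covers_half = one >= width / 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tobacco spend as a share of a poverty-line income
#'
#' @param spend GBP/week, >= 0.
#' @param threshold Unequivalised household poverty-line income, GBP/week,
#'   > 0.
#' @return Proportion of the threshold income.
#' @examples
#' spend_share_of_income(17.56, 392)  # about 0.045: at least 4%
#' @export
spend_share_of_income <- function(spend, threshold) {
  if (any(threshold <= 0)) stop("threshold must be > 0", call. = FALSE)
  if (any(spend < 0)) stop("spend must be >= 0", call. = FALSE)
  spend / threshold
}
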