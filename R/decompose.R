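# Children-count tables by marital group x family size and income band.

MARITAL_GROUPS <- c("married", "cohabiting", "single_female", "single_male")
SIZE_CLASSES <- c("1", "2", "3+")

#' Children below an income band edge, by marital group
#'
#' Applies the band percentage for each marital-status group to its
#' all-children count: `total = children x pct / 100`, unrounded, in
#' thousands. The single-parent group is split by gender (on the
#' all-children count, before the band percentage is applied; both single
#' groups share the same band percentage).
#'
#' @param inputs A [study_inputs()] object.
#' @param band `"poverty"` (below 60% of median) or `"below_upper"` (below
#'   70%).
#' @return Named numeric vector of child counts (thousands) for
#'   `married`, `cohabiting`, `single_female`, `single_male`.
#' @examples
#' band_totals(study_inputs(), "poverty")[["married"]]  # 8300 x 15% = 1245
#' @export
band_totals <- function(inputs, band = c("poverty", "below_upper")) {
  band <- match.arg(band)
  pct_field <- if (band == "poverty") "pct_poverty" else "pct_below_upper"
  pop <- inputs$population
  singles <- split_single_parents(pop$single$children, inputs$single_gender_split)
  all_children <- c(married = pop$married$children,
                    cohabiting = pop$cohabiting$children,
                    single_female = unname(singles[["single_female"]]),
                    single_male = unname(singles[["single_male"]]))
  pct <- c(married = pop$married[[pct_field]],
           cohabiting = pop$cohabiting[[pct_field]],
           single_female = pop$single[[pct_field]],
           single_male = pop$single[[pct_field]])
  all_children * pct / 100
}

#' Split single-parent children by parent gender
#'
#' Applies the single-parent gender split (91% female, 9% male from the ONS
#' Families and Households survey) to a children count.
#'
#' @param total_single_children Count (thousands), >= 0.
#' @param gender_split Named proportions for `female` and `male`, summing
#'   to 1.
#' @return Named vector `c(single_female = , single_male = )`.
#' @examples
#' split_single_parents(3000, c(female = 0.91, male = 0.09))
#' @export
split_single_parents <- function(total_single_children,
                                 gender_split = c(female = 0.91, male = 0.09)) {
  if (abs(sum(gender_split) - 1) > 1e-9)
    stop("single_gender_split must sum to 1", call. = FALSE)
  if (total_single_children < 0) stop("children count must be >= 0", call. = FALSE)
  c(single_female = total_single_children * gender_split[["female"]],
    single_male = total_single_children * gender_split[["male"]])
}

#' Split a group total across family-size classes
#'
#' Multiplies a marital-group child count by the proportions of children
#' living in households with one, two, or three-or-more children; the cells
#' sum exactly to the input total.
#'
#' @param group_total Count (thousands), >= 0.
#' @param proportions Named proportions over `"1"`, `"2"`, `"3+"`, summing
#'   to 1.
#' @return Named vector of three cells (thousands, unrounded).
#' @examples
#' split_by_family_size(1245, c("1" = 0.25, "2" = 0.39, "3+" = 0.36))
#' @export
split_by_family_size <- function(group_total, proportions) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("family-size proportions must sum to 1", call. = FALSE)
  if (group_total < 0) stop("children count must be >= 0", call. = FALSE)
  stats::setNames(group_total * as.numeric(proportions[SIZE_CLASSES]),
                  SIZE_CLASSES)
}

new_children_table <- function(cells, band) {
  structure(cells, class = "children_table", band = band)
}

#' Children table: marital group x family size for an income band
#'
#' Builds the full decomposition: band totals per marital group (singles
#' split by gender) spread over family-size classes with the band-specific
#' proportions. All cells are unrounded thousands; rounding happens only at
#' presentation.
#'
#' @inheritParams band_totals
#' @return A `children_table`: 4 x 3 numeric matrix (rows `married`,
#'   `cohabiting`, `single_female`, `single_male`; columns `1`, `2`, `3+`)
#'   with a `band` attribute.
#' @examples
#' children_table(study_inputs(), "poverty")
#' @export
children_table <- function(inputs, band = c("poverty", "below_upper")) {
  band <- match.arg(band)
  totals <- band_totals(inputs, band)
  props <- if (band == "poverty") inputs$family_size_props_poverty
           else inputs$family_size_props_below_upper
  cells <- t(vapply(totals, split_by_family_size, numeric(3),
                    proportions = props))
  dimnames(cells) <- list(MARITAL_GROUPS, SIZE_CLASSES)
  new_children_table(cells, band)
}

#' Between-band children table
#'
#' Cellwise difference of two children tables sharing the same layout,
#' typically below-70% minus below-60%: the children living between 60% and
#' 70% of median income. Small negative differences (rounding noise) are
#' clipped to zero; a difference more negative than the tolerance is an
#' error.
#'
#' @param below_upper,below_lower `children_table` objects with identical
#'   row and column structure.
#' @param tol Negative slack tolerated before clipping is refused
#'   (thousands).
#' @return A `children_table` with band attribute `"between"`.
#' @export
between_band_table <- function(below_upper, below_lower, tol = 1) {
  if (!identical(dimnames(below_upper), dimnames(below_lower)))
    stop("children tables have mismatched structure", call. = FALSE)
  d <- unclass(below_upper) - unclass(below_lower)
  if (any(d < -tol))
    stop("below_upper table is smaller than below_lower beyond tolerance",
         call. = FALSE)
  d[d < 0] <- 0
  new_children_table(d, "between")
}

#' @export
print.children_table <- function(x, digits = 0, ...) {
  cat(sprintf("Children (thousands), band: %s\n", attr(x, "band")))
  m <- cbind(unclass(x), total = rowSums(x))
  m <- rbind(m, total = colSums(m))
  print(round(m, digits))
  invisible(x)
}

#' @export
as.data.frame.children_table <- function(x, ...) {
  data.frame(marital_group = rep(rownames(x), times = ncol(x)),
             family_size = rep(colnames(x), each = nrow(x)),
             children_thousands = as.vector(unclass(x)),
             stringsAsFactors = FALSE)
}
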