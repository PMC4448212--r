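# Attribution of children to household smoker configurations.

SMOKER_CONFIGS <- c("single_mother_smokes", "single_father_smokes",
                    "married_one_smokes", "cohabiting_one_smokes",
                    "married_both_smoke", "cohabiting_both_smoke")

#' Children of smoking single parents
#'
#' For single-parent households the weighted smoking rate for single men or
#' women is applied directly to the child count.
#'
#' @param children Count (thousands), >= 0.
#' @param rate Smoking rate as a fraction in \[0, 1\].
#' @return Count (thousands, unrounded).
#' @examples
#' single_parent_attribution(150.15, 0.432)  # 64.9 -> printed 65
#' @export
single_parent_attribution <- function(children, rate) {
  if (any(rate < 0 | rate > 1)) stop("rate must lie in [0, 1]", call. = FALSE)
  if (any(children < 0)) stop("children count must be >= 0", call. = FALSE)
  children * rate
}

#' Children of smoking parents in two-parent households
#'
#' The expected number of smoking-parent instances is `S = children x
#' couple_rate` (couple_rate from [couple_smoking_rate()]). Of those
#' instances, `sole_fraction` (65%) are the only smoker in the home and the
#' rest live with a second smoking adult; a two-smoker household carries two
#' instances, so the both-smoke child count divides by two:
#' `one_smoker = S x sole_fraction`, `both_smoke = S x (1 - sole_fraction) / 2`.
#'
#' @param children Count (thousands), >= 0.
#' @param couple_rate Expected smoking parents per couple, >= 0 (may exceed
#'   1 under the marginal-sum approximation).
#' @param sole_fraction Proportion of smoking parents who are the sole
#'   smoker, in \[0, 1\].
#' @return Named vector `c(one_smoker = , both_smoke = )` (thousands).
#' @examples
#' couple_attribution(311.25, 0.455, 0.65)  # c(92.0, 24.8)
#' @export
couple_attribution <- function(children, couple_rate, sole_fraction = 0.65) {
  if (any(couple_rate < 0)) stop("couple_rate must be >= 0", call. = FALSE)
  if (sole_fraction < 0 || sole_fraction > 1)
    stop("sole_fraction must lie in [0, 1]", call. = FALSE)
  if (any(children < 0)) stop("children count must be >= 0", call. = FALSE)
  s <- children * couple_rate
  c(one_smoker = s * sole_fraction, both_smoke = s * (1 - sole_fraction) / 2)
}

#' Attribution table: children by household smoker configuration
#'
#' Converts a [children_table()] into counts of children living with
#' smokers, by configuration (smoking single mother/father; married or
#' cohabiting couple with one or both smoking) and family size. Single rows
#' use [single_parent_attribution()] with the single-man/woman weighted
#' rates; couple rows use [couple_attribution()].
#'
#' Because the couple rate is a marginal sum, the attributed children in a
#' stratum can exceed the children present; a warning is issued when this
#' happens.
#'
#' @param children A `children_table`.
#' @param prevalence A [weighted_prevalence()] object.
#' @param sole_fraction Sole-smoker proportion for couples (default 0.65).
#' @return An `attribution_table`: 6 x 3 matrix (rows the configurations,
#'   columns family-size classes), thousands, unrounded, with the source
#'   band as attribute.
#' @examples
#' at <- attribution_table(children_table(study_inputs(), "poverty"),
#'                         weighted_prevalence())
#' sum(at)  # about 1089.5 thousand: the "1.1 million" headline
#' @export
attribution_table <- function(children, prevalence, sole_fraction = 0.65) {
  r <- prevalence$rates / 100
  cells <- matrix(0, nrow = length(SMOKER_CONFIGS), ncol = ncol(children),
                  dimnames = list(SMOKER_CONFIGS, colnames(children)))
  cells["single_mother_smokes", ] <-
    single_parent_attribution(children["single_female", ], r["female", "single"])
  cells["single_father_smokes", ] <-
    single_parent_attribution(children["single_male", ], r["male", "single"])
  for (m in c("married", "cohabiting")) {
    cr <- couple_smoking_rate(prevalence, m)
    s <- children[m, ] * cr
    one <- s * sole_fraction
    both <- s * (1 - sole_fraction) / 2
    cells[paste0(m, "_one_smokes"), ] <- one
    cells[paste0(m, "_both_smoke"), ] <- both
    over <- one + both > children[m, ] + 1e-9
    if (any(over))
      warning(sprintf("%s: attributed children exceed children present in strata %s (marginal-sum approximation)",
                      m, paste(colnames(children)[over], collapse = ", ")),
              call. = FALSE)
  }
  structure(cells, class = "attribution_table", band = attr(children, "band"))
}

#' @export
print.attribution_table <- function(x, digits = 0, ...) {
  cat(sprintf("Children living with smokers (thousands), band: %s\n",
              attr(x, "band")))
  m <- cbind(unclass(x), total = rowSums(x))
  m <- rbind(m, total = colSums(m))
  print(round(m, digits))
  invisible(x)
}

#' @export
as.data.frame.attribution_table <- function(x, ...) {
  data.frame(configuration = rep(rownames(x), times = ncol(x)),
             family_size = rep(colnames(x), each = nrow(x)),
             children_thousands = as.vector(unclass(x)),
             stringsAsFactors = FALSE)
}
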