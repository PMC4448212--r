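# Printed survey aggregates used as study inputs, with provenance labels.

#' Default study inputs
#'
#' Returns the full set of printed survey parameters that drive the
#' estimation pipeline: HBAI 2011/12 population and income-band aggregates,
#' ONS Opinions and Lifestyle Survey (OPN) 2012 smoking prevalence and
#' consumption, the ONS single-parent gender split, the sole-smoker split for
#' two-parent households, TMA tobacco prices with the illicit discount, and
#' HMRC illicit-market shares. Counts are carried in thousands and all
#' derived quantities stay unrounded until presentation.
#'
#' Every top-level field carries a source label in the `"provenance"`
#' attribute (HBAI, OPN, ONS, TMA, HMRC, Jarvis, or an explicitly declared
#' modelling assumption); the labels are metadata only.
#'
#' @return An object of class `study_inputs`: a named list of parameters.
#'   See [validate_inputs()] for the invariants the fields must satisfy.
#' @examples
#' inp <- study_inputs()
#' inp$median_income          # 427 GBP/week, equivalised BHC
#' inp$prices[["licit_pack_20"]]
#' @export
study_inputs <- function() {
  inputs <- list(
    # income definition: equivalised net household income, before housing
    # costs (BHC), GBP/week; poverty line = 60% of the median
    median_income = 427,
    poverty_fraction = 0.60,
    upper_band_fraction = 0.70,
    # all-children counts (thousands) and % of children below each band,
    # by parental marital status
    population = list(
      married    = list(children = 8300, pct_poverty = 15, pct_below_upper = 24),
      cohabiting = list(children = 1900, pct_poverty = 20, pct_below_upper = 33),
      single     = list(children = 3000, pct_poverty = 22, pct_below_upper = 42)
    ),
    single_gender_split = c(female = 0.91, male = 0.09),
    # child-count-level proportions of children in households with 1, 2, 3+
    # children, by income band
    family_size_props_poverty     = c("1" = 0.25, "2" = 0.39, "3+" = 0.36),
    family_size_props_below_upper = c("1" = 0.23, "2" = 0.40, "3+" = 0.37),
    # smoking prevalence (%), routine-and-manual occupational group by sex,
    # general adult population, and by marital status (not sex-specific)
    base_prevalence = c(male = 33, female = 32),
    general_prevalence = 20,
    marital_prevalence = c(single = 27, married = 14, cohabiting = 33),
    # among smoking parents in two-parent households, proportion who are the
    # only smoking adult
    sole_smoker_fraction = 0.65,
    # consumption and product mix
    cigs_per_day = c(male = 13, female = 12),
    mainly_packeted_share = c(male = 0.59, female = 0.73),
    illicit_share = c(packeted = 0.07, hrt = 0.35),
    prices = c(licit_pack_20 = 7.72, licit_hrt_50g = 16.11,
               illicit_discount = 0.5),
    sticks_per_pack = 20,
    sticks_per_hrt_pack = 100,
    # fractions of children in the 60-70% band counted as drawn into
    # effective poverty, by household smoker count
    drawn_in_fractions = c(one_smoker = 0.5, two_smoker = 1.0),
    # modified OECD scale on the couple-without-children = 1 normalisation
    equivalence_scale = c(first_adult = 0.67, additional_14plus = 0.33,
                          child_under14 = 0.20),
    # microsimulation-only parameters (declared modelling assumptions)
    microsim = list(
      three_plus_children_dist = c("3" = 0.7, "4" = 0.2, "5" = 0.1),
      p_child_under14 = 0.7,
      income_floor_fraction = 0.30,
      income_ceiling_fraction = 1.60
    )
  )
  attr(inputs, "provenance") <- c(
    median_income = "HBAI", poverty_fraction = "HBAI",
    upper_band_fraction = "HBAI", population = "HBAI",
    single_gender_split = "ONS",
    family_size_props_poverty = "HBAI",
    family_size_props_below_upper = "HBAI",
    base_prevalence = "OPN", general_prevalence = "OPN",
    marital_prevalence = "OPN", sole_smoker_fraction = "Jarvis",
    cigs_per_day = "OPN", mainly_packeted_share = "OPN",
    illicit_share = "HMRC", prices = "TMA",
    sticks_per_pack = "convention", sticks_per_hrt_pack = "convention",
    drawn_in_fractions = "assumption", equivalence_scale = "OECD/HBAI",
    microsim = "assumption"
  )
  class(inputs) <- "study_inputs"
  inputs
}

#' Validate study inputs
#'
#' Checks every invariant the pipeline relies on and returns the violations
#' as a character vector (empty when the inputs are valid). Violations are
#' returned, not raised, so callers can report them all at once; each message
#' names the offending field.
#'
#' @param inputs A `study_inputs` object (or a plain list with the same
#'   fields).
#' @return Character vector of violation descriptions; `character(0)` if all
#'   invariants hold.
#' @examples
#' validate_inputs(study_inputs())   # character(0)
#' @export
validate_inputs <- function(inputs) {
  v <- character(0)
  bad <- function(msg) v <<- c(v, msg)

  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  check_pct <- function(x, field) {
    if (!num_ok(x) || any(x < 0) || any(x > 100))
      bad(sprintf("%s: percentages must lie in [0, 100]", field))
  }
  check_prop <- function(x, field) {
    if (!num_ok(x) || any(x < 0) || any(x > 1))
      bad(sprintf("%s: proportions must lie in [0, 1]", field))
  }
  sums_to_1 <- function(x, field) {
    if (num_ok(x) && abs(sum(x) - 1) > 1e-9)
      bad(sprintf("%s: must sum to 1 (got %.10g)", field, sum(x)))
  }

  if (!num_ok(inputs$median_income) || inputs$median_income <= 0)
    bad("median_income: must be a positive number")
  if (!num_ok(inputs$poverty_fraction) || !num_ok(inputs$upper_band_fraction) ||
      inputs$poverty_fraction <= 0 || inputs$upper_band_fraction > 1 ||
      inputs$poverty_fraction >= inputs$upper_band_fraction)
    bad("poverty_fraction/upper_band_fraction: need 0 < poverty_fraction < upper_band_fraction <= 1")

  for (g in names(inputs$population)) {
    p <- inputs$population[[g]]
    if (!num_ok(p$children) || p$children < 0)
      bad(sprintf("population.%s.children: counts must be >= 0", g))
    check_pct(p$pct_poverty, sprintf("population.%s.pct_poverty", g))
    check_pct(p$pct_below_upper, sprintf("population.%s.pct_below_upper", g))
  }

  check_prop(inputs$single_gender_split, "single_gender_split")
  sums_to_1(inputs$single_gender_split, "single_gender_split")
  for (f in c("family_size_props_poverty", "family_size_props_below_upper")) {
    check_prop(inputs[[f]], f)
    sums_to_1(inputs[[f]], f)
  }

  check_pct(inputs$base_prevalence, "base_prevalence")
  check_pct(inputs$general_prevalence, "general_prevalence")
  if (num_ok(inputs$general_prevalence) && inputs$general_prevalence <= 0)
    bad("general_prevalence: must be > 0 (used as a weighting denominator)")
  check_pct(inputs$marital_prevalence, "marital_prevalence")
  check_prop(inputs$sole_smoker_fraction, "sole_smoker_fraction")

  if (!num_ok(inputs$cigs_per_day) || any(inputs$cigs_per_day < 0))
    bad("cigs_per_day: must be >= 0")
  check_prop(inputs$mainly_packeted_share, "mainly_packeted_share")
  check_prop(inputs$illicit_share, "illicit_share")
  pr <- inputs$prices
  if (!num_ok(pr) || any(pr[c("licit_pack_20", "licit_hrt_50g")] < 0))
    bad("prices: licit prices must be >= 0")
  if (!num_ok(pr) || pr[["illicit_discount"]] <= 0 || pr[["illicit_discount"]] > 1)
    bad("prices.illicit_discount: must lie in (0, 1]")
  for (f in c("sticks_per_pack", "sticks_per_hrt_pack"))
    if (!num_ok(inputs[[f]]) || inputs[[f]] <= 0)
      bad(sprintf("%s: must be > 0", f))
  check_prop(inputs$drawn_in_fractions, "drawn_in_fractions")

  es <- inputs$equivalence_scale
  if (!num_ok(es) || any(es <= 0))
    bad("equivalence_scale: weights must be > 0")

  ms <- inputs$microsim
  check_prop(ms$three_plus_children_dist, "microsim.three_plus_children_dist")
  sums_to_1(ms$three_plus_children_dist, "microsim.three_plus_children_dist")
  check_prop(ms$p_child_under14, "microsim.p_child_under14")
  if (!num_ok(ms$income_floor_fraction) ||
      ms$income_floor_fraction < 0 ||
      ms$income_floor_fraction >= inputs$poverty_fraction)
    bad("microsim.income_floor_fraction: must lie in [0, poverty_fraction)")
  if (!num_ok(ms$income_ceiling_fraction) ||
      ms$income_ceiling_fraction <= inputs$upper_band_fraction)
    bad("microsim.income_ceiling_fraction: must exceed upper_band_fraction")

  v
}

# recursive override of defaults; named atomic vectors can be partially
# overridden element-by-element (YAML maps come back as lists)
merge_inputs <- function(defaults, override, path = "") {
  for (nm in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown input field: ", full, call. = FALSE)
    d <- defaults[[nm]]
    o <- override[[nm]]
    if (is.list(d) && is.list(o)) {
      defaults[[nm]] <- merge_inputs(d, o, full)
    } else if (is.atomic(d) && !is.null(names(d)) && (is.list(o) || !is.null(names(o)))) {
      o <- unlist(o)
      unknown <- setdiff(names(o), names(d))
      if (length(unknown))
        stop("unknown element ", unknown[1], " in field ", full, call. = FALSE)
      d[names(o)] <- o
      defaults[[nm]] <- d
    } else {
      defaults[[nm]] <- unlist(o)
    }
  }
  defaults
}

#' Load study inputs from a configuration file
#'
#' Reads a YAML configuration whose keys mirror [study_inputs()]; fields
#' present in the file override the packaged defaults, everything else falls
#' back to the default value. Named sub-fields (e.g. `cigs_per_day: {female:
#' 20}`) may be overridden individually. The merged inputs are validated and
#' a validation failure is an error naming the offending field.
#'
#' The packaged defaults file is at
#' `system.file("extdata", "study_inputs.yaml", package = "smokepov")`.
#'
#' @param path Path to a YAML file. An empty file yields the defaults.
#' @return A validated `study_inputs` object.
#' @seealso [study_inputs()], [write_inputs()]
#' @export
load_inputs <- function(path) {
  if (!file.exists(path))
    stop("input configuration file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  defaults <- study_inputs()
  if (is.null(raw) || length(raw) == 0) return(defaults)
  prov <- attr(defaults, "provenance")
  merged <- merge_inputs(unclass(defaults), raw)
  # fields actually changed no longer carry the packaged source label
  changed <- vapply(names(prov), function(nm)
    !isTRUE(all.equal(merged[[nm]], defaults[[nm]])), logical(1))
  prov[changed] <- "user"
  attr(merged, "provenance") <- prov
  class(merged) <- "study_inputs"
  issues <- validate_inputs(merged)
  if (length(issues))
    stop("invalid study inputs:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  merged
}

#' Write study inputs to a configuration file
#'
#' Serialises a `study_inputs` object as YAML in the schema read by
#' [load_inputs()], so defaults can be exported, edited and reloaded.
#'
#' @param inputs A `study_inputs` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_inputs <- function(inputs, path) {
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(listify(unclass(inputs)), path)
  invisible(path)
}

#' @export
print.study_inputs <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("Study inputs (printed survey aggregates)\n")
  cat(sprintf("  median equivalised income: GBP %g/week BHC; poverty line at %g%% of median\n",
              x$median_income, 100 * x$poverty_fraction))
  for (g in names(x$population)) {
    p <- x$population[[g]]
    cat(sprintf("  %-11s %5g thousand children; %g%% in poverty, %g%% below %g%% of median\n",
                paste0(g, ":"), p$children, p$pct_poverty, p$pct_below_upper,
                100 * x$upper_band_fraction))
  }
  cat(sprintf("  smoking prevalence (routine & manual): male %g%%, female %g%%\n",
              x$base_prevalence[["male"]], x$base_prevalence[["female"]]))
  cat(sprintf("  sole-smoker fraction in couples: %g\n", x$sole_smoker_fraction))
  cat("  sources: ", paste(unique(unname(prov)), collapse = ", "), "\n", sep = "")
  invisible(x)
}
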