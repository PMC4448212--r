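# Weekly tobacco quantities, spend per product type, and average spend.

PRODUCT_TYPES <- c("licit_packeted", "licit_hrt", "illicit_packeted", "illicit_hrt")

#' Cigarettes smoked per week
#'
#' @param cigs_per_day Cigarettes/day, >= 0.
#' @return Sticks/week (`7 x cigs_per_day`).
#' @examples
#' weekly_sticks(12)  # 84
#' @export
weekly_sticks <- function(cigs_per_day) {
  if (any(cigs_per_day < 0)) stop("cigs_per_day must be >= 0", call. = FALSE)
  7 * cigs_per_day
}

#' Packs purchased per week
#'
#' Manufactured ("packeted") cigarettes come in packs of 20; a 50 g pouch of
#' hand-rolling tobacco (HRT) makes approximately 100 cigarettes.
#'
#' @param sticks_per_week Cigarettes/week, >= 0.
#' @param form `"packeted"` or `"hrt"`.
#' @param sticks_per_pack,sticks_per_hrt_pack Sticks per unit purchased.
#' @return Packs (or pouches)/week.
#' @examples
#' weekly_packs(84, "packeted")  # 4.2
#' weekly_packs(91, "hrt")       # 0.91
#' @export
weekly_packs <- function(sticks_per_week, form = c("packeted", "hrt"),
                         sticks_per_pack = 20, sticks_per_hrt_pack = 100) {
  form <- match.arg(form)
  if (any(sticks_per_week < 0)) stop("sticks must be >= 0", call. = FALSE)
  sticks_per_week / if (form == "packeted") sticks_per_pack else sticks_per_hrt_pack
}

#' Weekly spend on one product
#'
#' @param packs_per_week Packs/week, >= 0.
#' @param unit_price GBP per pack/pouch, >= 0.
#' @return GBP/week.
#' @examples
#' product_spend(4.2, 7.72)  # 32.42
#' @export
product_spend <- function(packs_per_week, unit_price) {
  if (any(packs_per_week < 0) || any(unit_price < 0))
    stop("packs and prices must be >= 0", call. = FALSE)
  packs_per_week * unit_price
}

#' Product-type mix of smokers
#'
#' Splits smokers of one sex over the four product types. `mainly_packeted`
#' is the share smoking mainly manufactured cigarettes (dual users are
#' already folded into the category they mostly smoke); the illicit shares
#' then split each form into licit and illicit.
#'
#' @param mainly_packeted Proportion smoking mainly manufactured cigarettes.
#' @param illicit_packeted_share,illicit_hrt_share Illicit shares of each
#'   form (defaults 0.07 and 0.35).
#' @return Named proportions over the four product types, summing to 1.
#' @examples
#' product_mix(0.73)  # female mix: 0.679, 0.176, 0.051, 0.094
#' @export
product_mix <- function(mainly_packeted, illicit_packeted_share = 0.07,
                        illicit_hrt_share = 0.35) {
  p <- c(mainly_packeted, illicit_packeted_share, illicit_hrt_share)
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  c(licit_packeted = mainly_packeted * (1 - illicit_packeted_share),
    licit_hrt = (1 - mainly_packeted) * (1 - illicit_hrt_share),
    illicit_packeted = mainly_packeted * illicit_packeted_share,
    illicit_hrt = (1 - mainly_packeted) * illicit_hrt_share)
}

#' Average weekly tobacco spend
#'
#' Convex combination of the per-product spends with the product mix as
#' weights.
#'
#' @param spend Named GBP/week by product type.
#' @param mix Named proportions by product type, summing to 1.
#' @return GBP/week.
#' @export
average_spend <- function(spend, mix) {
  if (abs(sum(mix) - 1) > 1e-9) stop("mix must sum to 1", call. = FALSE)
  sum(spend[PRODUCT_TYPES] * mix[PRODUCT_TYPES])
}

# round a mix to whole percentages, largest-remainder correction so the
# rounded proportions still sum to exactly 1
round_mix_percent <- function(mix) {
  pct <- mix * 100
  r <- floor(pct)
  short <- round(sum(pct)) - sum(r)
  if (short > 0) {
    idx <- order(pct - r, decreasing = TRUE)[seq_len(short)]
    r[idx] <- r[idx] + 1
  }
  r / 100
}

#' Weekly tobacco expenditure profile by sex
#'
#' Builds the full cost-of-smoking table: weekly sticks, packs by form,
#' per-product prices and spends (illicit prices are the licit price times
#' the illicit discount, so illicit HRT is 16.11 / 2 = 8.055), the
#' product-type mix, and the overall average spend per smoker.
#'
#' `mix_rounding = "percent"` rounds the mix to integer percentages before
#' averaging, replicating published tables that present the mix that way;
#' the default uses the unrounded mix.
#'
#' @param inputs A [study_inputs()] object.
#' @param mix_rounding `"none"` (default) or `"percent"`.
#' @return An `expenditure_profile`: per sex, a list with `sticks_per_week`,
#'   `packs` (by form), `prices`, `spend` and `mix` (by product type) and
#'   `average`; plus the `mix_rounding` used.
#' @examples
#' ep <- expenditure_profile(study_inputs())
#' ep$female$spend[["licit_packeted"]]  # 32.42
#' @export
expenditure_profile <- function(inputs = study_inputs(),
                                mix_rounding = c("none", "percent")) {
  mix_rounding <- match.arg(mix_rounding)
  pr <- inputs$prices
  prices <- c(licit_packeted = unname(pr[["licit_pack_20"]]),
              licit_hrt = unname(pr[["licit_hrt_50g"]]),
              illicit_packeted = unname(pr[["licit_pack_20"]] * pr[["illicit_discount"]]),
              illicit_hrt = unname(pr[["licit_hrt_50g"]] * pr[["illicit_discount"]]))
  out <- list()
  for (sex in c("female", "male")) {
    sticks <- weekly_sticks(inputs$cigs_per_day[[sex]])
    packs <- c(packeted = weekly_packs(sticks, "packeted",
                                       inputs$sticks_per_pack,
                                       inputs$sticks_per_hrt_pack),
               hrt = weekly_packs(sticks, "hrt",
                                  inputs$sticks_per_pack,
                                  inputs$sticks_per_hrt_pack))
    spend <- prices * packs[c("packeted", "hrt", "packeted", "hrt")]
    names(spend) <- PRODUCT_TYPES
    mix <- product_mix(inputs$mainly_packeted_share[[sex]],
                       inputs$illicit_share[["packeted"]],
                       inputs$illicit_share[["hrt"]])
    mix_used <- if (mix_rounding == "percent") round_mix_percent(mix) else mix
    out[[sex]] <- list(sticks_per_week = sticks, packs = packs,
                       prices = prices, spend = spend, mix = mix,
                       mix_used = mix_used,
                       average = average_spend(spend, mix_used))
  }
  structure(c(out, list(mix_rounding = mix_rounding)),
            class = "expenditure_profile")
}

#' @export
print.expenditure_profile <- function(x, ...) {
  cat("Weekly tobacco expenditure per smoker (GBP)\n")
  for (sex in c("female", "male")) {
    s <- x[[sex]]
    cat(sprintf("  %-6s %g sticks/week; spend by type: %s; average %.2f\n",
                sex, s$sticks_per_week,
                paste(sprintf("%s %.2f", names(s$spend), s$spend), collapse = ", "),
                s$average))
  }
  invisible(x)
}

#' @export
as.data.frame.expenditure_profile <- function(x, ...) {
  rows <- lapply(c("female", "male"), function(sex) {
    s <- x[[sex]]
    data.frame(sex = sex, product_type = PRODUCT_TYPES,
               price_gbp = unname(s$prices),
               packs_per_week = unname(s$packs[c("packeted", "hrt", "packeted", "hrt")]),
               weekly_spend_gbp = unname(s$spend),
               mix_proportion = unname(s$mix[PRODUCT_TYPES]),
               average_spend_gbp = s$average,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
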