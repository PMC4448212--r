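# Full aggregate pipeline: the main estimator and its methods.

#' Estimate the contribution of parental smoking to child poverty
#'
#' Runs the full closed-form pipeline on a set of printed survey aggregates:
#' poverty and upper-band thresholds (modified-OECD equivalisation),
#' marital-status-weighted smoking prevalence, children tables by marital
#' group and family size for the below-60% and below-70% bands, attribution
#' of children to household smoker configurations in the poverty band and
#' the 60-70% band, the tobacco expenditure profile, and the drawn-into-
#' poverty counts under the half/all rule. The result is a pure function of
#' the inputs.
#'
#' @param inputs A [study_inputs()] object (defaults to the packaged survey
#'   values).
#' @param sole_smoker_fraction Override for the sole-smoker split
#'   (defaults to the value in `inputs`).
#' @return An object of class `smoke_poverty` with components `inputs`,
#'   `thresholds`, `prevalence`, `children` (poverty / below-upper /
#'   between tables), `attribution` (poverty and between-band tables),
#'   `expenditure`, `drawn_in`, `diagnostic` (band-width table) and
#'   `headline`: `with_smoker_poverty` and `drawn_in`, both in thousands of
#'   children.
#' @examples
#' fit <- smoke_poverty()
#' fit                      # headline figures
#' coef(fit)                # the two headline counts (thousands)
#' @seealso [summary.smoke_poverty()], [simulate.smoke_poverty()],
#'   [sensitivity_sweep()], [write_report()]
#' @export
smoke_poverty <- function(inputs = study_inputs(),
                          sole_smoker_fraction = inputs$sole_smoker_fraction) {
  issues <- validate_inputs(inputs)
  if (length(issues))
    stop("invalid study inputs:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)

  thresholds <- c(
    equivalised_poverty = income_threshold(inputs$median_income,
                                           inputs$poverty_fraction),
    equivalised_upper = income_threshold(inputs$median_income,
                                         inputs$upper_band_fraction))

  prevalence <- weighted_prevalence(inputs$base_prevalence,
                                    inputs$general_prevalence,
                                    inputs$marital_prevalence)

  ct_pov <- children_table(inputs, "poverty")
  ct_upper <- children_table(inputs, "below_upper")
  ct_between <- between_band_table(ct_upper, ct_pov)

  at_pov <- attribution_table(ct_pov, prevalence, sole_smoker_fraction)
  at_between <- attribution_table(ct_between, prevalence, sole_smoker_fraction)

  expenditure <- expenditure_profile(inputs)
  drawn <- drawn_in_counts(at_between, inputs$drawn_in_fractions)

  structure(list(
    inputs = inputs,
    thresholds = thresholds,
    prevalence = prevalence,
    children = list(poverty = ct_pov, below_upper = ct_upper,
                    between = ct_between),
    attribution = list(poverty = at_pov, between = at_between),
    expenditure = expenditure,
    drawn_in = drawn,
    diagnostic = band_width_diagnostic(inputs),
    headline = c(with_smoker_poverty = sum(at_pov),
                 drawn_in = drawn$total_drawn_in)
  ), class = "smoke_poverty")
}

#' @export
print.smoke_poverty <- function(x, ...) {
  cat("Parental smoking and child poverty - aggregate pipeline\n")
  cat(sprintf("  poverty line: GBP %.1f/week equivalised (%.0f%% of median GBP %g)\n",
              x$thresholds[["equivalised_poverty"]],
              100 * x$inputs$poverty_fraction, x$inputs$median_income))
  cat(sprintf("  children in poverty:                      %5.0f thousand\n",
              sum(x$children$poverty)))
  cat(sprintf("  ... living with at least one smoker:      %5.0f thousand (%.1f million)\n",
              x$headline[["with_smoker_poverty"]],
              round(x$headline[["with_smoker_poverty"]] / 1000, 1)))
  cat(sprintf("  drawn into poverty by tobacco spend:      %5.0f thousand\n",
              x$headline[["drawn_in"]]))
  invisible(x)
}

#' Summarise a smoke_poverty fit
#'
#' Prints the intermediate tables at the precision each is conventionally
#' reported at: prevalence to one decimal, child counts to the nearest
#' thousand, pound amounts to two decimals.
#'
#' @param object A [smoke_poverty()] fit.
#' @param ... Unused.
#' @export
summary.smoke_poverty <- function(object, ...) {
  structure(list(fit = object), class = "summary.smoke_poverty")
}

#' @export
print.summary.smoke_poverty <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nWeighted smoking prevalence (%):\n")
  print(round_half_up(fit$prevalence$rates, 1))
  cat("\nChildren in poverty (thousands):\n")
  print(fit$children$poverty)
  cat("\nChildren 60-70% of median (thousands):\n")
  print(fit$children$between)
  cat("\nChildren in poverty living with smokers (thousands):\n")
  print(fit$attribution$poverty)
  cat("\nWeekly tobacco spend per smoker (GBP):\n")
  print(fit$expenditure)
  cat("\nDrawn into effective poverty (thousands):\n")
  print(fit$drawn_in)
  invisible(x)
}

#' Headline estimates from a fit
#'
#' @param object A [smoke_poverty()] fit.
#' @param ... Unused.
#' @return Named vector: children in poverty living with at least one
#'   smoking parent, and children drawn into effective poverty, both in
#'   thousands.
#' @export
coef.smoke_poverty <- function(object, ...) object$headline

#' Run the microsimulation oracle for a fit
#'
#' `simulate()` on a fit runs the household-level Monte-Carlo counterpart
#' of the aggregate pipeline ([microsim_estimates()]) with the same inputs,
#' so the two can be compared with [compare_with_aggregate()].
#'
#' @param object A [smoke_poverty()] fit.
#' @param nsim Number of Monte-Carlo replicates.
#' @param seed Integer seed.
#' @param n_households Households per replicate.
#' @param ... Passed to [microsim_estimates()].
#' @return A `microsim_estimates` object.
#' @export
simulate.smoke_poverty <- function(object, nsim = 20, seed = 1,
                                   n_households = 200000, ...) {
  microsim_estimates(object$inputs, n_households = n_households,
                     n_replicates = nsim, seed = seed, ...)
}

#' @export
plot.smoke_poverty <- function(x, ...) {
  tot <- rowSums(x$attribution$poverty)
  old <- graphics::par(mar = c(5, 11, 3, 1))
  on.exit(graphics::par(old))
  graphics::barplot(rev(tot), horiz = TRUE, las = 1,
                    names.arg = rev(gsub("_", " ", names(tot))),
                    xlab = "children in poverty (thousands)",
                    main = "Children in poverty living with smokers", ...)
  invisible(x)
}

# set a dotted-path field (e.g. "base_prevalence.male") in a study_inputs
set_input_field <- function(inputs, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  assign_rec <- function(x, parts) {
    p <- parts[[1]]
    if (!p %in% names(x)) stop("unknown input field: ", path, call. = FALSE)
    if (length(parts) == 1) x[[p]] <- value
    else x[[p]] <- assign_rec(x[[p]], parts[-1])
    x
  }
  assign_rec(inputs, parts)
}

#' Sensitivity sweep over input parameters
#'
#' Re-runs the aggregate pipeline over a grid of input values and returns
#' the headline figures per grid point in long format. Grid names are
#' dotted paths into [study_inputs()] (e.g. `"base_prevalence.male"`); the
#' full Cartesian product of the supplied values is evaluated. An empty
#' grid performs a single default run.
#'
#' @param inputs Baseline [study_inputs()].
#' @param grid Named list of numeric vectors of parameter values.
#' @return Data frame: one row per grid point with the parameter values,
#'   `with_smoker_poverty` and `drawn_in` (thousands).
#' @examples
#' sensitivity_sweep(grid = list(`base_prevalence.male` = c(33, 39)))
#' @export
sensitivity_sweep <- function(inputs = study_inputs(), grid = list()) {
  if (length(grid) == 0) {
    fit <- smoke_poverty(inputs)
    return(data.frame(with_smoker_poverty = fit$headline[["with_smoker_poverty"]],
                      drawn_in = fit$headline[["drawn_in"]]))
  }
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(pts)), function(i) {
    inp <- inputs
    for (nm in names(pts)) inp <- set_input_field(inp, nm, pts[i, nm])
    fit <- smoke_poverty(inp)
    cbind(pts[i, , drop = FALSE],
          data.frame(with_smoker_poverty = fit$headline[["with_smoker_poverty"]],
                     drawn_in = fit$headline[["drawn_in"]]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a report of a fit to disk
#'
#' Emits one CSV per table (prevalence, children by band, attribution,
#' expenditure, drawn-in), a JSON summary of the headline figures and
#' thresholds, and a plain-text run manifest with input provenance. The
#' summary JSON is a pure function of the fit, so reruns with the same
#' inputs are byte-identical; timestamps go to the manifest only. If the
#' target directory already contains a report, a versioned subdirectory
#' (`run-2`, `run-3`, ...) is created instead of overwriting.
#'
#' @param fit A [smoke_poverty()] fit.
#' @param dir Output directory (created if missing).
#' @return The directory written to, invisibly.
#' @export
write_report <- function(fit, dir) {
  if (dir.exists(dir) && file.exists(file.path(dir, "summary.json"))) {
    v <- 2
    while (dir.exists(file.path(dir, paste0("run-", v)))) v <- v + 1
    dir <- file.path(dir, paste0("run-", v))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0)
    stop("output directory is not writable: ", dir, call. = FALSE)

  w <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  prev <- fit$prevalence$rates
  w(data.frame(sex = rep(rownames(prev), ncol(prev)),
               marital = rep(colnames(prev), each = nrow(prev)),
               prevalence_pct = round_half_up(as.vector(prev), 1)),
    "table1_prevalence.csv")
  round_ct <- function(ct) {
    d <- as.data.frame(ct); d$children_thousands <- round(d$children_thousands); d
  }
  w(round_ct(fit$children$poverty), "table2_children_poverty.csv")
  w(round_ct(fit$attribution$poverty), "table3_children_with_smokers.csv")
  ep <- as.data.frame(fit$expenditure)
  for (col in c("price_gbp", "weekly_spend_gbp", "average_spend_gbp"))
    ep[[col]] <- round(ep[[col]], 2)
  ep$mix_proportion <- round(ep$mix_proportion, 3)
  w(ep, "table4_expenditure.csv")
  w(round_ct(fit$children$between), "table5_children_between_bands.csv")
  d6 <- as.data.frame(fit$drawn_in)
  for (col in setdiff(names(d6), "configuration")) d6[[col]] <- round(d6[[col]])
  w(d6, "table6_drawn_in.csv")

  summary_obj <- list(
    thresholds = as.list(round(fit$thresholds, 2)),
    headline_thousands = as.list(round(unclass(fit$headline), 1)),
    children_in_poverty_thousands = round(sum(fit$children$poverty)),
    headline_presentation = list(
      with_smoker = sprintf("%.1f million", round(fit$headline[["with_smoker_poverty"]] / 1000, 1)),
      drawn_in = sprintf("%d thousand", round(fit$headline[["drawn_in"]]))))
  jsonlite::write_json(summary_obj, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  prov <- attr(fit$inputs, "provenance")
  manifest <- c("smokepov run manifest",
                paste0("package version: ",
                       as.character(utils::packageVersion("smokepov"))),
                paste0("written: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
                "input provenance:",
                paste0("  ", names(prov), ": ", prov))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
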