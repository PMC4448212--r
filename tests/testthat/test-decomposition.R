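test_that("band totals and splits reproduce the published poverty table", {
  inp <- inputs_default
  totals <- band_totals(inp, "poverty")
  expect_equal(unname(totals[["married"]]), 8300 * 0.15)  # 1245
  expect_equal(split_single_parents(3000, c(female = 0.91, male = 0.09)),
               c(single_female = 2730, single_male = 270))
  cells <- split_by_family_size(1245, c("1" = 0.25, "2" = 0.39, "3+" = 0.36))
  expect_equal(round(cells), c("1" = 311, "2" = 486, "3+" = 448))

  ct <- children_table(inp, "poverty")
  expect_equal(round(sum(ct)), 2285)
  expect_equal(unname(round(ct["married", ])), c(311, 486, 448))
  expect_equal(unname(round(ct["single_female", ])), c(150, 234, 216))
})

test_that("the below-70% table and its grand total match the published values", {
  ct <- children_table(inputs_default, "below_upper")
  expect_equal(unname(round(ct["married", ])), c(458, 797, 737))
  expect_equal(unname(round(rowSums(ct)[["cohabiting"]])), 627)
  expect_lt(abs(sum(ct) - 3878), 2)
  # single-female cells derive from the recovered below-70 proportions
  expect_equal(unname(round(ct["single_female", ])), c(264, 459, 424),
               tolerance = 1e-8)
})

test_that("between-band differencing matches the published cells and clips noise", {
  upper <- children_table(inputs_default, "below_upper")
  lower <- children_table(inputs_default, "poverty")
  between <- between_band_table(upper, lower)
  expect_true(all(abs(unclass(between)["married", ] - c(147, 311, 289)) <= 1))
  expect_lt(abs(sum(between) - 1593), 2)
  # identical tables difference to zero; sub-tolerance negatives clip to 0
  zero <- between_band_table(lower, lower)
  expect_true(all(unclass(zero) == 0))
  jitter <- lower
  jitter[1, 1] <- jitter[1, 1] + 0.5
  expect_true(all(unclass(between_band_table(lower, jitter)) >= 0))
  expect_error(between_band_table(lower, jitter, tol = 0.1), "tolerance")
})

test_that("decomposition conserves counts for arbitrary valid inputs", {
  set.seed(42)
  for (i in 1:20) {
    inp <- inputs_default
    for (g in names(inp$population)) {
      inp$population[[g]]$children <- runif(1, 100, 10000)
      p60 <- runif(1, 1, 50)
      inp$population[[g]]$pct_poverty <- p60
      inp$population[[g]]$pct_below_upper <- p60 + runif(1, 0, 30)
    }
    pr <- runif(3); pr <- pr / sum(pr)
    names(pr) <- c("1", "2", "3+")
    inp$family_size_props_poverty <- pr
    inp$family_size_props_below_upper <- pr
    ct <- children_table(inp, "poverty")
    totals <- band_totals(inp, "poverty")
    # family-size cells sum to the marital group totals
    expect_equal(rowSums(ct), totals)
    # single split conserves the single total
    expect_equal(sum(totals[c("single_female", "single_male")]),
                 inp$population$single$children *
                   inp$population$single$pct_poverty / 100)
    # between + lower = upper, cellwise
    upper <- children_table(inp, "below_upper")
    between <- between_band_table(upper, ct)
    expect_equal(unclass(between) + unclass(ct), unclass(upper),
                 ignore_attr = TRUE)
    expect_true(all(unclass(ct) >= 0))
  }
  expect_error(split_by_family_size(100, c("1" = 0.5, "2" = 0.4, "3+" = 0.3)),
               "sum to 1")
  expect_error(split_single_parents(100, c(female = 0.5, male = 0.4)),
               "sum to 1")
})
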