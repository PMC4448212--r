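test_that("the half/all rule reproduces the published drawn-in table", {
  di <- fit_default$drawn_in
  expect_true(all(abs(di$with_smoker_by_config - printed_table6_with_smoker) <= 1))
  expect_true(all(abs(di$drawn_in_by_config - printed_table6_drawn) <= 1))
  expect_lt(abs(di$total_with_smoker - 758), 3)
  expect_gte(di$total_drawn_in, 431)
  expect_lte(di$total_drawn_in, 435)
  # row totals are halved unrounded totals, e.g. 236 -> 118
  expect_equal(round(di$drawn_in_by_config[["single_mother_smokes"]]), 118)
  expect_equal(di$drawn_in_by_config[["married_both_smoke"]],
               di$with_smoker_by_config[["married_both_smoke"]])
})

test_that("drawn-in counts are monotone in the assumption fractions", {
  at <- fit_default$attribution$between
  base <- drawn_in_counts(at)
  expect_true(all(base$drawn_in_by_config <= base$with_smoker_by_config + 1e-9))
  zero <- drawn_in_counts(at, c(one_smoker = 0, two_smoker = 0))
  expect_equal(zero$total_drawn_in, 0)
  full <- drawn_in_counts(at, c(one_smoker = 1, two_smoker = 1))
  expect_equal(full$total_drawn_in, full$total_with_smoker)
  grid <- seq(0, 1, by = 0.25)
  prev <- -1
  for (f in grid) {
    cur <- drawn_in_counts(at, c(one_smoker = f, two_smoker = f))$total_drawn_in
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_error(drawn_in_counts(at, c(one_smoker = 1.5, two_smoker = 1)),
               "fractions")
})

test_that("the band-width diagnostic compares spend against the 60-70% gap", {
  d <- band_width_diagnostic(inputs_default)
  couple <- d[d$composition == "couple_2children", ]
  expect_equal(couple$band_width_gbp, 0.1 * 427 * 1.53)
  expect_equal(couple$two_smoker_spend_gbp,
               fit_default$expenditure$female$average +
                 fit_default$expenditure$male$average)
  single <- d[d$composition == "single_1child", ]
  expect_equal(single$band_width_gbp, 0.1 * 427 * 0.87)
  # one-smoker spend covers over half of the single-parent band width
  expect_true(single$one_smoker_covers_half)
})

test_that("spend shares of poverty-line income match the affordability figures", {
  # illicit cigarettes for a man against the two-parent two-child line
  share <- spend_share_of_income(17.56, 392)
  expect_gte(share, 0.04)
  expect_equal(share, 0.0448, tolerance = 0.01)
  expect_equal(spend_share_of_income(0, 392), 0)
  expect_equal(round(spend_share_of_income(32.42, 392), 4), 0.0827)
  expect_error(spend_share_of_income(10, 0), "threshold")
})
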