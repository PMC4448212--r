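# Monte-Carlo checks run at a fixed seed; sampling error bands are 3 SEs.
# Children are clustered within households, so child-weighted shares use the
# linearised (ratio-estimator) SE over households, not a naive binomial.

three_se <- function(p, n) 3 * sqrt(p * (1 - p) / n)

ratio_se <- function(w, z) {
  theta <- sum(w * z) / sum(w)
  sqrt(sum((w * (z - theta))^2)) / sum(w)
}

test_that("household generation is deterministic given the seed", {
  h1 <- generate_households(inputs_default, 5000, seed = 11)
  h2 <- generate_households(inputs_default, 5000, seed = 11)
  expect_identical(h1, h2)
  h3 <- generate_households(inputs_default, 5000, seed = 12)
  expect_false(identical(h1$income, h3$income))
  a1 <- assign_smoking(h1, seed = 3)
  a2 <- assign_smoking(h2, seed = 3)
  expect_identical(a1, a2)
})

test_that("generated households recover the configured marginals", {
  n <- 150000
  hh <- generate_households(inputs_default, n, seed = 21)
  # child-level marital shares
  for (g in c("married", "cohabiting")) {
    z <- as.numeric(hh$marital == g)
    target <- inputs_default$population[[g]]$children / 13200
    got <- sum(hh$n_children * z) / sum(hh$n_children)
    expect_lt(abs(got - target), 3 * ratio_se(hh$n_children, z))
  }
  # child-level poverty fraction per marital group
  for (g in c("married", "single_female")) {
    sub <- hh[hh$marital == g, ]
    target <- inputs_default$population[[if (g == "married") "married" else "single"]]$pct_poverty / 100
    z <- as.numeric(sub$band == "poverty")
    got <- sum(sub$n_children * z) / sum(sub$n_children)
    expect_lt(abs(got - target), 3 * ratio_se(sub$n_children, z))
  }
  # family-size proportions inside the poverty band
  pov <- hh[hh$band == "poverty", ]
  cls <- ifelse(pov$n_children >= 3, "3+", as.character(pov$n_children))
  for (k in c("1", "2", "3+")) {
    target <- inputs_default$family_size_props_poverty[[k]]
    z <- as.numeric(cls == k)
    got <- sum(pov$n_children * z) / sum(pov$n_children)
    expect_lt(abs(got - target), 3 * ratio_se(pov$n_children, z))
  }
  # incomes sit inside their band edges
  expect_true(all(hh$eq_income[hh$band == "between"] >= 256.2 - 1e-9))
  expect_true(all(hh$eq_income[hh$band == "between"] <= 298.9 + 1e-9))
})

test_that("smoking assignment recovers prevalence, mix and the sole-smoker split", {
  n <- 150000
  hh <- assign_smoking(generate_households(inputs_default, n, seed = 31), seed = 32)
  r <- weighted_prevalence()$rates / 100
  for (m in c("married", "cohabiting")) {
    sub <- hh[hh$marital == m, ]
    expect_equal(mean(sub$smoker_male), unname(r["male", m]),
                 tolerance = three_se(r["male", m], nrow(sub)) / r["male", m])
    expect_equal(mean(sub$smoker_female), unname(r["female", m]),
                 tolerance = three_se(r["female", m], nrow(sub)) / r["female", m])
  }
  sf <- hh[hh$marital == "single_female", ]
  expect_equal(mean(sf$smoker_female), unname(r["female", "single"]),
               tolerance = three_se(r["female", "single"], nrow(sf)) / r["female", "single"])
  # sole-smoker fraction among partnered smoking parents
  couples <- hh[hh$n_adults == 2, ]
  n_one <- sum(couples$n_smokers == 1)
  n_both <- sum(couples$n_smokers == 2)
  sole <- n_one / (n_one + 2 * n_both)
  expect_equal(sole, 0.65, tolerance = three_se(0.65, n_one + 2 * n_both) / 0.65)
})

test_that("concordance calibration solves the sole-smoker identity in closed form", {
  cc <- calibrate_concordance(inputs_default)
  expect_equal(cc$married$p_both, 0.35 * (0.231 + 0.224) / 2)
  expect_equal(cc$cohabiting$p_both, 0.35 * (0.5445 + 0.528) / 2)
  # the attribution identity: 2 P(both) / (p_m + p_f) = 1 - sole fraction
  expect_equal(2 * cc$married$p_both / (cc$married$p_male + cc$married$p_female),
               0.35)
  # sole fraction 1 forces P(both) = 0 where marginals allow it
  inp1 <- inputs_default
  inp1$sole_smoker_fraction <- 1
  inp1$marital_prevalence[["cohabiting"]] <- 20  # keep p_m + p_f below 1
  cc1 <- calibrate_concordance(inp1)
  expect_equal(cc1$married$p_both, 0)
  expect_equal(cc1$cohabiting$p_both, 0)
  # ... and is infeasible when the marginals force dual-smoker couples
  inp1b <- inputs_default
  inp1b$sole_smoker_fraction <- 1
  expect_error(calibrate_concordance(inp1b), "lower bound")
  # infeasible target: asymmetric marginals with no sole smokers
  inp2 <- inputs_default
  inp2$sole_smoker_fraction <- 0
  inp2$base_prevalence <- c(male = 60, female = 20)
  inp2$marital_prevalence[["married"]] <- 30
  expect_error(calibrate_concordance(inp2), "exceeds the smaller marginal")
})

test_that("concordance zero gives independent couple smoking", {
  hh <- assign_smoking(generate_households(inputs_default, 150000, seed = 41),
                       concordance = 0, seed = 42)
  mar <- hh[hh$marital == "married", ]
  p_both <- mean(mar$smoker_male & mar$smoker_female)
  target <- 0.231 * 0.224
  expect_equal(p_both, target, tolerance = three_se(target, nrow(mar)) / target)
  # zero prevalence: nobody smokes
  inp0 <- inputs_default
  inp0$base_prevalence <- c(male = 0, female = 0)
  hh0 <- assign_smoking(generate_households(inp0, 2000, seed = 5),
                        inputs = inp0, seed = 6)
  expect_equal(sum(hh0$n_smokers), 0)
})

test_that("degenerate configurations behave: empty bands and free tobacco", {
  inp <- inputs_default
  for (g in names(inp$population)) {
    inp$population[[g]]$pct_poverty <- 0
    inp$population[[g]]$pct_below_upper <- 0
  }
  hh <- generate_households(inp, 20000, seed = 51)
  expect_true(all(hh$eq_income > 298.9))
  # zero prices: nobody is drawn in
  free <- inputs_default
  free$prices[["licit_pack_20"]] <- 0
  free$prices[["licit_hrt_50g"]] <- 0
  ms <- microsim_estimates(free, n_households = 20000, n_replicates = 2, seed = 61)
  est <- ms$estimates
  expect_equal(est$mean[est$quantity == "drawn_in"], 0)
})

test_that("the oracle refuses comparisons across differing inputs", {
  ms <- microsim_estimates(inputs_default, n_households = 10000,
                           n_replicates = 2, seed = 71)
  other <- inputs_default
  other$median_income <- 430
  fit_other <- smoke_poverty(other)
  expect_error(compare_with_aggregate(ms, fit_other), "refusing")
  cmp <- compare_with_aggregate(ms, fit_default)
  expect_s3_class(cmp, "microsim_comparison")
  expect_true(all(c("rel_diff", "within") %in% names(cmp)))
})
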