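test_that("packaged defaults satisfy every invariant and carry provenance", {
  inp <- study_inputs()
  expect_length(validate_inputs(inp), 0)
  prov <- attr(inp, "provenance")
  expect_setequal(names(prov), names(inp))
  expect_true(all(c("HBAI", "OPN", "ONS", "TMA", "HMRC", "Jarvis") %in% prov))
  # headline defaults
  expect_equal(inp$median_income, 427)
  expect_equal(unname(inp$prices[["licit_pack_20"]]), 7.72)
  expect_equal(inp$sole_smoker_fraction, 0.65)
})

test_that("config files override defaults field-by-field and fall back otherwise", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("cigs_per_day:\n  female: 20", f)
  inp <- load_inputs(f)
  expect_equal(unname(inp$cigs_per_day[["female"]]), 20)
  expect_equal(unname(inp$cigs_per_day[["male"]]), 13)  # untouched default
  expect_equal(inp$median_income, 427)
  expect_equal(attr(inp, "provenance")[["cigs_per_day"]], "user")

  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_equal(load_inputs(empty), study_inputs())

  expect_error(load_inputs(file.path(tempdir(), "no-such-file.yaml")),
               "not found")
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("single_gender_split:\n  female: 0.8\n  male: 0.1", bad)
  expect_error(load_inputs(bad), "single_gender_split")
  unk <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_field: 3", unk)
  expect_error(load_inputs(unk), "unknown input field")
})

test_that("defaults round-trip through the shipped configuration file", {
  shipped <- system.file("extdata", "study_inputs.yaml", package = "smokepov")
  expect_true(file.exists(shipped))
  expect_equal(load_inputs(shipped), study_inputs())

  f <- withr::local_tempfile(fileext = ".yaml")
  write_inputs(study_inputs(), f)
  expect_equal(load_inputs(f), study_inputs())
})

test_that("validate_inputs returns named violations instead of raising", {
  inp <- study_inputs()
  inp$poverty_fraction <- 0.8   # above the 0.7 upper band
  v <- validate_inputs(inp)
  expect_length(v, 1)
  expect_match(v, "poverty_fraction")

  inp2 <- study_inputs()
  inp2$prices[["licit_pack_20"]] <- -1
  expect_match(validate_inputs(inp2), "prices", all = FALSE)

  inp3 <- study_inputs()
  inp3$single_gender_split[["male"]] <- 0.2
  expect_match(validate_inputs(inp3), "single_gender_split", all = FALSE)
})
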