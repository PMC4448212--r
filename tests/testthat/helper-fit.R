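# shared fixtures: the default fit is cheap to build once and reused
fit_default <- smoke_poverty()
inputs_default <- study_inputs()

# published reference tables the pipeline should reproduce (thousands,
# rounded as printed)
printed_table3 <- rbind(
  single_mother_smokes  = c(65, 101, 93),
  single_father_smokes  = c(6.6, 10, 9.5),
  married_one_smokes    = c(92, 143, 132),
  cohabiting_one_smokes = c(66, 103, 95),
  married_both_smoke    = c(25, 39, 36),
  cohabiting_both_smoke = c(18, 28, 26))
colnames(printed_table3) <- c("1", "2", "3+")

printed_table6_with_smoker <- c(
  single_mother_smokes = 236, single_father_smokes = 24,
  married_one_smokes = 220, cohabiting_one_smokes = 172,
  married_both_smoke = 60, cohabiting_both_smoke = 47)
printed_table6_drawn <- c(
  single_mother_smokes = 118, single_father_smokes = 12,
  married_one_smokes = 110, cohabiting_one_smokes = 86,
  married_both_smoke = 60, cohabiting_both_smoke = 47)
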