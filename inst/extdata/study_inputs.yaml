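median_income: 427.0
poverty_fraction: 0.6
upper_band_fraction: 0.7
population:
  married:
    children: 8300.0
    pct_poverty: 15.0
    pct_below_upper: 24.0
  cohabiting:
    children: 1900.0
    pct_poverty: 20.0
    pct_below_upper: 33.0
  single:
    children: 3000.0
    pct_poverty: 22.0
    pct_below_upper: 42.0
single_gender_split:
  female: 0.91
  male: 0.09
family_size_props_poverty:
  '1': 0.25
  '2': 0.39
  3+: 0.36
family_size_props_below_upper:
  '1': 0.23
  '2': 0.4
  3+: 0.37
base_prevalence:
  male: 33.0
  female: 32.0
general_prevalence: 20.0
marital_prevalence:
  single: 27.0
  married: 14.0
  cohabiting: 33.0
sole_smoker_fraction: 0.65
cigs_per_day:
  male: 13.0
  female: 12.0
mainly_packeted_share:
  male: 0.59
  female: 0.73
illicit_share:
  packeted: 0.07
  hrt: 0.35
prices:
  licit_pack_20: 7.72
  licit_hrt_50g: 16.11
  illicit_discount: 0.5
sticks_per_pack: 20.0
sticks_per_hrt_pack: 100.0
drawn_in_fractions:
  one_smoker: 0.5
  two_smoker: 1.0
equivalence_scale:
  first_adult: 0.67
  additional_14plus: 0.33
  child_under14: 0.2
microsim:
  three_plus_children_dist:
    '3': 0.7
    '4': 0.2
    '5': 0.1
  p_child_under14: 0.7
  income_floor_fraction: 0.3
  income_ceiling_fraction: 1.6
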