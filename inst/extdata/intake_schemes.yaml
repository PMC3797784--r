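# Built-in reference-intake schemes for iron (mg/day).
#
# us_rda:       US Recommended Dietary Allowance (8 default, 18 premenopausal,
#               27 pregnant); premenopausal increment 10 mg/day per 80 mL/month.
# uk_rni:       UK Reference Nutrient Intake (8.7 default, 14.8 premenopausal);
#               increment 6.1 mg/day per 80 mL/month.
# study_hybrid: US base allowances paired with an explicit increment override
#               of 6.1 mg/day, the effective ruleset of the validation cohort's
#               published derived values.
#
# User configs use the same layout; entries with a preset's scheme_id replace
# that preset.
schemes:
- scheme_id: us_rda
  base_default: 8.0
  base_premenopausal: 18.0
  base_pregnant: 27.0
  menstrual_reference_volume: 80.0
- scheme_id: uk_rni
  base_default: 8.7
  base_premenopausal: 14.8
  menstrual_reference_volume: 80.0
- scheme_id: study_hybrid
  base_default: 8.0
  base_premenopausal: 18.0
  base_pregnant: 27.0
  increment_override: 6.1
  menstrual_reference_volume: 80.0
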