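# Illustrative risk-model configuration for the ten-factor caries screening
# instrument.  The odds ratios below are NOT fitted values from any
# surveillance cohort (the original instrument's fitted odds ratios were
# published only in a figure, without numeric values in the text); they are
# plausible illustrative magnitudes chosen so that mixed profiles span all
# three risk bands.  Factor order reflects the instrument's hierarchical
# ordering of contributions.
cutoffs:
  low_max: 2.6
  mod_min: 2.7
  mod_max: 4.4
  high_min: 4.5
factors:
  - name: fluoridation
    levels: [fluoridated, nonfluoridated]
    referent: fluoridated
    odds_ratios:
      nonfluoridated: 2.1
  - name: smoke_exposure
    levels: [not_exposed, exposed]
    referent: not_exposed
    odds_ratios:
      exposed: 1.9
  - name: race
    levels: [white, black, hispanic, other]
    referent: white
    odds_ratios:
      black: 1.8
      hispanic: 1.6
      other: 1.3
  - name: age
    levels: ["13-14", "15-16", "17-18"]
    referent: "13-14"
    odds_ratios:
      "15-16": 1.3
      "17-18": 1.5
  - name: locale
    levels: [metro, rural]
    referent: metro
    odds_ratios:
      rural: 1.5
  - name: tobacco_use
    levels: [nonuser, user]
    referent: nonuser
    odds_ratios:
      user: 1.6
  - name: bmi
    levels: [normal, overweight]
    referent: normal
    odds_ratios:
      overweight: 1.4
  - name: insurance
    levels: [insured, uninsured]
    referent: insured
    odds_ratios:
      uninsured: 1.4
  - name: sex
    levels: [female, male]
    referent: female
    odds_ratios:
      male: 1.2
  - name: sealants
    levels: [present, absent]
    referent: present
    odds_ratios:
      absent: 1.5
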