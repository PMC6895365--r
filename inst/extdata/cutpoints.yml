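# Cut-point registry used only at the translation stage, never before
# metric computation.  threshold_mg values are wrist-referenced unless
# stated otherwise; walk bands are ballpark placeholders the user should
# override with population-appropriate values.
mvpa_200:
  threshold_mg: 200
  population: children/adolescents
  wear_site: wrist
  source: common wrist MVPA cut-point
mvpa_250:
  threshold_mg: 250
  population: children/adolescents
  wear_site: wrist
  source: more stringent wrist MVPA cut-point
vig_700:
  threshold_mg: 700
  population: children
  wear_site: wrist
  source: vigorous-activity threshold
very_vig_1200:
  threshold_mg: 1200
  population: children
  wear_site: wrist
  source: very vigorous (running/jumping) threshold
slow_walk:
  threshold_mg: 100
  population: generic
  wear_site: wrist
  source: approximate slow-walk band (user-adjustable ballpark)
brisk_walk:
  threshold_mg: 250
  population: generic
  wear_site: wrist
  source: approximate brisk-walk band (user-adjustable ballpark)
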