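# Schema for a DILIrank-style export with verbose concern categories
# and metabolism given in percent.
percent_fractions: true
columns:
  drug_id: compound_name
  daily_dose_mg: daily_dose_mg
  logp: logp
  metabolism_fraction: hepatic_metabolism_pct
  urinary_unchanged_fraction: urinary_unchanged_pct
sources:
  chen:
    column: dili_concern
    positive: ["Most-DILI-concern", "vMost-DILI-concern"]
    negative: ["No-DILI-concern", "vNo-DILI-concern"]
  xu:
    column: xu_label
    positive: ["Positive"]
    negative: ["Negative"]
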