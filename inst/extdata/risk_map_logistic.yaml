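# Example logistic score-to-probability link: p = plogis(intercept + slope * score).
# These coefficients approximate the default link, which is calibrated to the
# observed per-score mortalities at 10/20/30/40 points of the German
# single-centre validation cohort; see gpospom::default_risk_map().
mode: logistic
logistic:
  intercept: -7.1589
  slope: 0.1442
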