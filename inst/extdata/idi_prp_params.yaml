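# Two-strategy ART-delivery decision model: pharmacy-only refill program
# (PRP) vs standard of care (SOC) at a large urban HIV clinic, Kampala.
# Costs are annual per patient in 2009 US$. The `residual` category carries
# the difference between each strategy's published perspective total and the
# sum of its published components, so that component-level sensitivity
# analysis and the published totals coexist.
strategies:
  soc:
    p_fir: 0.196
    followup_months: 15.1
    costs:
      art: 243
      other_drugs: 35
      radiology: 2
      laboratory: 34
      personnel: 31
      overhead_capital: 141
      transport: 20
      lost_patient_time: 16
      residual: 133
    totals:
      limited_societal: 655
      moh: 610
  prp:
    p_fir: 0.186
    followup_months: 12.8
    costs:
      art: 243
      other_drugs: 35
      radiology: 2
      laboratory: 34
      personnel: 10
      overhead_capital: 141
      transport: 20
      lost_patient_time: 4
      residual: 31
    totals:
      limited_societal: 520
      moh: 496
n_patients:
  soc: 251
  prp: 578
psa:
  n_iter: 10000
  seed: 2009
sensitivity:
  cost_low_factor: 0.5
  cost_high_factor: 2.0
  prob_delta: 0.2
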