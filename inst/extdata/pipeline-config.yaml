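# concernews pipeline configuration template.
# Every key is optional; omitted keys take the documented package defaults.
# Unknown keys are rejected so typos fail loudly.

seed: 1

sim:
  n_encounters: 500
  event_fraction: 0.3          # deterioration-enriched benchmark cohort
  behavioral_onset_hours: 48   # concern ramp starts this long before the event
  physiological_onset_hours: 6 # vital drift starts this long before the event
  drift_max: 1.0               # 0 disables physiological deterioration
  # base_rates / concern_multipliers: named maps over the 13 event streams,
  # see ?sim_config for names and defaults
  vitals_schedule: [0, 4, 8, 12, 16, 20]
  hospice_fraction: 0.02

features:
  window_hours: 12             # trailing aggregation window
  common_threshold: 0.0416667  # 1/24: at-or-above-uniform hour-of-day share

scoring:
  horizon_hours: 12            # "event within next H hours" training target
  cutpoint_quantiles: [0.80, 0.95]  # yellow / red training-score quantiles
  folds: 2                     # cross-fitting folds (split by encounter)
  staleness_hours: 12          # comparator vitals carry-forward limit
  regularize: ridge            # ridge | none
  min_train_events: 5

evaluation:
  horizons: "1:48"             # lead-time horizon grid (hours)
  smoothing: 0.5               # add-k smoothing constant
  convention: exact            # exact | cumulative horizon reading
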