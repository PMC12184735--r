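# Demo configuration for `emews run --config demo.yaml --out-dir results/`
# Simulates a two-week ward census and audits it under the phase-3 policy.
seed: 7
phase:
  name: P3
simulator:
  n_patients: 20
  mix:
    uncomplicated: 0.3
    epidural: 0.6
    deterioration: 0.1
  start: "2019-01-01T00:00:00Z"
  span_days: 14
  artifact_rate: 0.05
audit:
  timezone: UTC
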