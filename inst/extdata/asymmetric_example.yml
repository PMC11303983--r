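# Example configuration: system asymmetry (oxygen-tolerant sulfur
# reducers) combined with reduced sulfide-diffusivity variation.
# Unspecified keys fall back to the symmetric defaults
# (symtip::default_run_config()).
model:
  H_O: 140
environment:
  n_steps: 41
  factor: 0.6
analysis:
  metric: raw
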