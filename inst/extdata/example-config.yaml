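# example stcsim run configuration
# parameter names follow the standard symbol table; note that the bare key
# N (spine count) may be written unquoted - it is restored from YAML's
# boolean interpretation
params:
  mu_Pd: 5.0e-2      # 50x the standard basal PRP level
  "N": 2
experiment: window
experiment_args:
  s_min: -60
  s_max: 60
  step: 10
output_dir: out
sample_dt: 10
solver:
  rtol: 1.0e-8
  atol: 1.0e-10
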