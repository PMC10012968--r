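# Example run configuration: coupled model, supine, 4.8 L/min.
# Any key from default_run_config() can be overridden here.
posture: supine
cardiac_output_L_min: 4.8
mode: coupled
seed: 1
geometry:
  n_acini: 2000
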