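# Synthetic measured-beam-size table on the assumed clinical nozzle
experiment: synth
seed: 1
nozzle:
  preset: icpo_current
  monitor_offsets_cm: [-40, -20, 0, 20, 40]
synth:
  noise_rel: 0.01
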