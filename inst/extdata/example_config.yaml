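# Example experiment configuration: the standard serial-passage scenario
# with a 1% initial variant fraction and a 1.5 Gy exposure at plating.
preset: serial
seeding:
  variant_fraction: 0.01
radiation:
  dose: 1.5
  alpha_normal: 0.39
  alpha_variant: 0.022
  time_hours: 0
seed: 1
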