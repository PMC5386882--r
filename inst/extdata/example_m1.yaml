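name: M1
metamodel: yes
classes:
- kind: constant
  gamma: 2.6
  maf: 0.01
  count: 2
  gamma_free: yes
  maf_free: yes
  count_free: yes
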