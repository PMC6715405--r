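# Example of an arbitrary (non-preset) stochastic reaction system declared
# inline: the classic bistable autocatalytic network. The deterministic rate
# equations admit a single steady state in parts of parameter space where the
# stochastic process still jumps between locally stable count levels --
# a minimal illustration of why molecule-level simulation can matter.
preset: ~
model: custom
network:
  name: schlogl
  species:
    - name: A
      D: 0.1
  reactions:
    - label: S1           # 2A -> 3A
      reactants: {A: 2}
      products: {A: 3}
      k: 0.03
    - label: S2           # 3A -> 2A
      reactants: {A: 3}
      products: {A: 2}
      k: 0.0001
    - label: S3           # 0 -> A
      reactants: {}
      products: {A: 1}
      k: 200.0
    - label: S4           # A -> 0
      reactants: {A: 1}
      products: {}
      k: 3.5
geometry:
  dim: 2
  radius: 4
  height: 1
  shell_fraction: 0.04
stop:
  max_events: 200000
  max_time: "Inf"
seed: 1
snapshot:
  every_events: 20000
  dt: ~
analysis:
  threshold: ~
  threshold_fraction: 0.5
  connectivity: face
  min_size: 1
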