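grid:
  width: 1
  height: 2
  wrap: none
models:
  delta_notch:
    file: delta_notch_two_cell-delta_notch.sbml
assignment: delta_notch
inputs:
  Green:
    kind: integration
    rules:
      '1': Red>=1 [1:1] atleast 1
initial:
  components:
    Green: 0
    Red: 0
simulation:
  scheme: synchronous
  max_steps: 100
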