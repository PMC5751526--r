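genes:
- x1
- x2
controls:
- u
nodes:
- - expr: x1 | u
    prob: '0.3'
  - expr: x1 & x2
    prob: '0.7'
- - expr: x1 & !u
    prob: '0.2'
  - expr: x2
    prob: '0.8'
q: '0.3'
p: '0.1'
costs:
  control:
  - u: '1'
    cost: '1'
  terminal:
  - state: '00'
    cost: '0'
  - state: '01'
    cost: '2'
  - state: '10'
    cost: '4'
  - state: '11'
    cost: '6'
  default: '0'
horizon: 4
initial:
  x: '11'
  d:
  - 1
  - 1
  s: 0
  per: '00'
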