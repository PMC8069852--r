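rois:
  theta:
    name: theta
    Ge: 5.17
    we: 75.0
    Gs: 4.45
    ws: 25.0
    Gf: 57.1
    wf: 300.0
    e0: 2.5
    r: 0.56
    v0: 6.0
    C:
      pe: 15.0
      ps: 53.0
      pf: 10.0
      ep: 15.0
      sp: 35.0
      fp: 10.0
      fs: 10.0
      ff: 0.0
    Ip: 400.0
    If: 0.0
  alpha:
    name: alpha
    Ge: 5.17
    we: 75.0
    Gs: 4.45
    ws: 50.0
    Gf: 57.1
    wf: 300.0
    e0: 2.5
    r: 0.56
    v0: 6.0
    C:
      pe: 15.0
      ps: 73.0
      pf: 10.0
      ep: 15.0
      sp: 35.0
      fp: 10.0
      fs: 10.0
      ff: 0.0
    Ip: 200.0
    If: 0.0
  beta:
    name: beta
    Ge: 5.17
    we: 75.0
    Gs: 4.45
    ws: 30.0
    Gf: 40.0
    wf: 200.0
    e0: 2.5
    r: 0.56
    v0: 6.0
    C:
      pe: 15.0
      ps: 8.0
      pf: 42.0
      ep: 15.0
      sp: 35.0
      fp: 35.0
      fs: 0.0
      ff: 0.0
    Ip: 400.0
    If: 0.0
  gamma:
    name: gamma
    Ge: 5.17
    we: 120.0
    Gs: 4.45
    ws: 30.0
    Gf: 57.1
    wf: 300.0
    e0: 2.5
    r: 0.7
    v0: 6.0
    C:
      pe: 15.0
      ps: 0.0
      pf: 27.0
      ep: 15.0
      sp: 35.0
      fp: 56.0
      fs: 0.0
      ff: 0.0
    Ip: 400.0
    If: 0.0
connections:
- source: theta
  target: gamma
  weight: 20.0
  sign: excitatory
- source: alpha
  target: theta
  weight: 20.0
  sign: inhibitory
- source: alpha
  target: beta
  weight: 20.0
  sign: inhibitory
- source: alpha
  target: gamma
  weight: 20.0
  sign: inhibitory
- source: beta
  target: gamma
  weight: 20.0
  sign: excitatory
- source: gamma
  target: theta
  weight: 20.0
  sign: excitatory
- source: gamma
  target: beta
  weight: 20.0
  sign: excitatory
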