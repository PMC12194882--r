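# Minimal example chip: a first-order planar Hilbert capillary on cone
# supports. Short parameter names follow the membrane layout symbols
# (ld = lumen diameter, pd = pore diameter, ps = pore spacing, all um);
# the long names (lumen_diameter, ...) are accepted as aliases.
seed: 1
path:
  source: hilbert
  order: 1
  dims: 2
  step: 200
  degree: 3
  corner_fillet_radius: 20
capillary:
  ld: 40
  pd: 5
  ps: 8
  wall: 10
supports:
  strategy: cone
  taper_angle: 15
  tip_radius: 10
  cone_spacing: 150
chip:
  base_thickness: 20
  base_margin: 100
output:
  dir: forge_out
  decimate: 0.95
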