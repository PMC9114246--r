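# Whey-permeate lactic acid fermentation case study: three geometrically
# similar stirred tanks. SI units throughout (m, m^3, s^-1, Pa s, kg m^-3).
# Impeller diameters are anchored to the reported Reynolds numbers at the
# nominal agitation speed (no diameters were reported for this campaign).
cases:
  lab:
    fluid:
      density: 1060
      dynamic_viscosity: 0.0068
      kinematic_viscosity: 6.36e-06
      cell_size_range_um: [0.9, 1.9]
    vessel:
      total_volume: 0.03
      working_volume: 0.003
      working_height: 0.18
      Z_over_T: 1.37
      H_over_T: 3
      D_over_T: 0.45
    impeller:
      type: RTB
      power_number: 5
      count: 2
      reynolds_anchor: {reynolds: 1810, speed: 3.333}
    speed: 3.333
  pilot:
    fluid:
      density: 1060
      dynamic_viscosity: 0.0057
      kinematic_viscosity: 5.37e-06
      cell_size_range_um: [0.9, 1.9]
    vessel:
      total_volume: 0.1
      working_volume: 0.1
      working_height: 0.65
      Z_over_T: 1.61
      H_over_T: 3
      D_over_T: 0.45
    impeller:
      type: RTB
      power_number: 5
      count: 2
      reynolds_anchor: {reynolds: 20400, speed: 3.333}
    speed: 3.333
  industrial:
    fluid:
      density: 1060
      dynamic_viscosity: 0.0057
      kinematic_viscosity: 5.37e-06
      cell_size_range_um: [0.9, 1.9]
    vessel:
      total_volume: 300
      working_volume: 207
      working_height: 11.47
      Z_over_T: 2.55
      H_over_T: 3
      D_over_T: 0.45
    impeller:
      type: RTB
      power_number: 5
      count: 2
      reynolds_anchor: {reynolds: 2553190, speed: 3.333}
    speed: 3.333
# Transition-regime power number for the Rushton turbine, read off the
# published Po-Re chart at the laboratory Reynolds number (~1.8e3).
correlation:
  - {type: RTB, transition_po: 4.58}
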