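# Default 21-compartment closed-loop lumped-parameter configuration.
# Describes a healthy adult at rest. Values are standard for this model
# family (textbook/literature summary values for regional resistances,
# compliances and unstressed volumes), assembled for this package; they are
# a representative parameter set, not a transcription of any single source.
# Units: R in mmHg*s/mL, C in mL/mmHg, E in mmHg/mL, volumes in mL, times in s.
name: human_default
total_blood_volume: 5000
dt: 0.0005
fs: 200
heart_rate: 72
resp_rate: 12
p_it_mean: -4.0
p_it_amp: 2.0
systolic_k: 0.3
arrest_elastance: diastolic
valve_mode_post_arrest: sealed_cardiac
settle_s: 60
record_from: -60
horizon_post_arrest: 615
aortic_arch_index: 0
right_atrium_index: 15
abp_index: 6
co_edge: {from: 16, to: 17}
init_pressures: {arterial: 90.0, venous: 6.0, pulmonary: 14.0, cardiac: 8.0}
compartments:
  - {id: 0,  name: aortic_arch,          kind: arterial,  C: 0.28, V_unstressed: 21,   thoracic: true}
  - {id: 1,  name: brachiocephalic,      kind: arterial,  C: 0.13, V_unstressed: 5,    thoracic: false}
  - {id: 2,  name: upper_body_arteries,  kind: arterial,  C: 0.42, V_unstressed: 50,   thoracic: false}
  - {id: 3,  name: upper_body_veins,     kind: venous,    C: 7.0,  V_unstressed: 650,  thoracic: false, venous_tone: true}
  - {id: 4,  name: superior_vena_cava,   kind: venous,    C: 1.3,  V_unstressed: 33,   thoracic: true}
  - {id: 5,  name: thoracic_aorta,       kind: arterial,  C: 0.21, V_unstressed: 16,   thoracic: true}
  - {id: 6,  name: abdominal_aorta,      kind: arterial,  C: 0.10, V_unstressed: 10,   thoracic: false}
  - {id: 7,  name: renal_arteries,       kind: arterial,  C: 0.21, V_unstressed: 20,   thoracic: false}
  - {id: 8,  name: renal_veins,          kind: venous,    C: 5.0,  V_unstressed: 150,  thoracic: false, venous_tone: true}
  - {id: 9,  name: splanchnic_arteries,  kind: arterial,  C: 0.42, V_unstressed: 50,   thoracic: false}
  - {id: 10, name: splanchnic_veins,     kind: venous,    C: 50.0, V_unstressed: 1146, thoracic: false, venous_tone: true}
  - {id: 11, name: leg_arteries,         kind: arterial,  C: 0.42, V_unstressed: 100,  thoracic: false}
  - {id: 12, name: leg_veins,            kind: venous,    C: 27.0, V_unstressed: 716,  thoracic: false, venous_tone: true}
  - {id: 13, name: abdominal_veins,      kind: venous,    C: 1.3,  V_unstressed: 79,   thoracic: false, venous_tone: true}
  - {id: 14, name: inferior_vena_cava,   kind: venous,    C: 0.5,  V_unstressed: 33,   thoracic: true}
  - {id: 15, name: right_atrium,         kind: cardiac,   E_min: 0.30, E_max: 0.74, V_unstressed: 14, thoracic: true, act_delay: 0.0, init_like: venous}
  - {id: 16, name: right_ventricle,      kind: cardiac,   E_min: 0.07, E_max: 1.30, V_unstressed: 46, thoracic: true, act_delay: 0.12}
  - {id: 17, name: pulmonary_arteries,   kind: pulmonary, C: 3.4,  V_unstressed: 160,  thoracic: true}
  - {id: 18, name: pulmonary_veins,      kind: pulmonary, C: 9.0,  V_unstressed: 430,  thoracic: true}
  - {id: 19, name: left_atrium,          kind: cardiac,   E_min: 0.50, E_max: 0.61, V_unstressed: 24, thoracic: true, act_delay: 0.0, init_like: pulmonary}
  - {id: 20, name: left_ventricle,       kind: cardiac,   E_min: 0.10, E_max: 2.50, V_unstressed: 55, thoracic: true, act_delay: 0.12}
connections:
  - {from: 20, to: 0,  R: 0.007, valve: cardiac}        # aortic valve
  - {from: 0,  to: 1,  R: 0.010}
  - {from: 1,  to: 2,  R: 0.060}
  - {from: 2,  to: 3,  R: 4.90,  valve: microvascular, reflex_resistance: true}
  - {from: 3,  to: 4,  R: 0.110}
  - {from: 4,  to: 15, R: 0.028}
  - {from: 0,  to: 5,  R: 0.011}
  - {from: 5,  to: 6,  R: 0.010}
  - {from: 6,  to: 7,  R: 0.100}
  - {from: 7,  to: 8,  R: 4.10,  valve: microvascular, reflex_resistance: true}
  - {from: 8,  to: 13, R: 0.110}
  - {from: 6,  to: 9,  R: 0.070}
  - {from: 9,  to: 10, R: 3.00,  valve: microvascular, reflex_resistance: true}
  - {from: 10, to: 13, R: 0.070}
  - {from: 6,  to: 11, R: 0.090}
  - {from: 11, to: 12, R: 4.50,  valve: microvascular, reflex_resistance: true}
  - {from: 12, to: 13, R: 0.100}
  - {from: 13, to: 14, R: 0.019}
  - {from: 14, to: 15, R: 0.008}
  - {from: 15, to: 16, R: 0.005, valve: cardiac}        # tricuspid valve
  - {from: 16, to: 17, R: 0.003, valve: cardiac}        # pulmonic valve
  - {from: 17, to: 18, R: 0.080}
  - {from: 18, to: 19, R: 0.010}
  - {from: 19, to: 20, R: 0.010, valve: cardiac}        # mitral valve
reflex:
  enabled: true
  window_n: 250
  tick_hz: 200
  setpoints: {arterial: 95.0, pulse: 35.0, venous: 3.0}
  limits: {abr: 18.0, cpr: 5.0}
  # Triangular unit-area kernels: (delay, peak, end) in s, discretized at
  # rate_hz. Gains per effector: g_hr additive (bpm per unit scaled error),
  # g_contract / g_resist fractional (per unit), g_vu additive (mL per unit).
  # Sign convention: positive (hypertensive) error lowers HR, contractility
  # and resistance and raises unstressed volume.
  arcs:
    - {name: abr_hr_para,   source: abp, class: abr, delay: 0.1, peak: 0.5,   end: 1.0,   rate_hz: 200, g_hr: -0.8}
    - {name: abr_hr_symp,   source: abp, class: abr, delay: 2.0, peak: 5.0,   end: 30.0,  rate_hz: 20,  g_hr: -0.6}
    - {name: abr_contract,  source: abp, class: abr, delay: 2.0, peak: 5.0,   end: 30.0,  rate_hz: 20,  g_contract: -0.015}
    - {name: abr_resist,    source: abp, class: abr, delay: 2.0, peak: 6.0,   end: 40.0,  rate_hz: 20,  g_resist: -0.09}
    - {name: abr_pp_symp,   source: pp,  class: abr, delay: 2.0, peak: 5.0,   end: 30.0,  rate_hz: 20,  g_hr: -0.3, g_contract: -0.008}
    - {name: abr_vtone,     source: abp, class: abr, delay: 10.0, peak: 170.0, end: 290.0, rate_hz: 10, g_vu: 42.0}
    - {name: cpr_resist,    source: cvp, class: cpr, delay: 5.0, peak: 30.0,  end: 60.0,  rate_hz: 20,  g_resist: -0.04}
    - {name: cpr_vtone,     source: cvp, class: cpr, delay: 300.0, peak: 480.0, end: 620.0, rate_hz: 10, g_vu: 169.0}
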