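name: pig_calibrated
total_blood_volume: 3799.020047250061
dt: 0.0005
fs: 200
heart_rate: 100.0
resp_rate: 20.0
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
co_edge:
  from: 16
  to: 17
init_pressures:
  arterial: 53.682032999675
  venous: 10.885008035604
  pulmonary: 30.278541602124
  cardiac: 21.627529715803
compartments:
- id: 0
  name: aortic_arch
  kind: arterial
  C: 0.1743
  V_unstressed: 13.0725
  thoracic: yes
- id: 1
  name: brachiocephalic
  kind: arterial
  C: 0.080925
  V_unstressed: 3.1125
  thoracic: no
- id: 2
  name: upper_body_arteries
  kind: arterial
  C: 0.26145
  V_unstressed: 31.125
  thoracic: no
- id: 3
  name: upper_body_veins
  kind: venous
  C: 4.3575
  V_unstressed: 404.625
  thoracic: no
  venous_tone: yes
- id: 4
  name: superior_vena_cava
  kind: venous
  C: 0.80925
  V_unstressed: 20.5425
  thoracic: yes
- id: 5
  name: thoracic_aorta
  kind: arterial
  C: 0.130725
  V_unstressed: 9.96
  thoracic: yes
- id: 6
  name: abdominal_aorta
  kind: arterial
  C: 0.06225
  V_unstressed: 6.225
  thoracic: no
- id: 7
  name: renal_arteries
  kind: arterial
  C: 0.130725
  V_unstressed: 12.45
  thoracic: no
- id: 8
  name: renal_veins
  kind: venous
  C: 3.1125
  V_unstressed: 93.375
  thoracic: no
  venous_tone: yes
- id: 9
  name: splanchnic_arteries
  kind: arterial
  C: 0.26145
  V_unstressed: 31.125
  thoracic: no
- id: 10
  name: splanchnic_veins
  kind: venous
  C: 31.125
  V_unstressed: 713.385
  thoracic: no
  venous_tone: yes
- id: 11
  name: leg_arteries
  kind: arterial
  C: 0.26145
  V_unstressed: 62.25
  thoracic: no
- id: 12
  name: leg_veins
  kind: venous
  C: 16.8075
  V_unstressed: 445.71
  thoracic: no
  venous_tone: yes
- id: 13
  name: abdominal_veins
  kind: venous
  C: 0.80925
  V_unstressed: 49.1775
  thoracic: no
  venous_tone: yes
- id: 14
  name: inferior_vena_cava
  kind: venous
  C: 0.31125
  V_unstressed: 20.5425
  thoracic: yes
- id: 15
  name: right_atrium
  kind: cardiac
  E_min: 0.481927710843
  E_max: 0.506024096386
  V_unstressed: 8.715
  thoracic: yes
  act_delay: 0.0
  init_like: venous
- id: 16
  name: right_ventricle
  kind: cardiac
  E_min: 0.112449799197
  E_max: 0.394603481009
  V_unstressed: 28.635
  thoracic: yes
  act_delay: 0.12
- id: 17
  name: pulmonary_arteries
  kind: pulmonary
  C: 2.1165
  V_unstressed: 99.6
  thoracic: yes
- id: 18
  name: pulmonary_veins
  kind: pulmonary
  C: 5.6025
  V_unstressed: 267.675
  thoracic: yes
- id: 19
  name: left_atrium
  kind: cardiac
  E_min: 0.803212851406
  E_max: 0.843373493976
  V_unstressed: 14.94
  thoracic: yes
  act_delay: 0.0
  init_like: pulmonary
- id: 20
  name: left_ventricle
  kind: cardiac
  E_min: 0.160642570281
  E_max: 0.758852848094
  V_unstressed: 34.2375
  thoracic: yes
  act_delay: 0.12
connections:
- from: 20
  to: 0
  R: 0.01124497992
  valve: cardiac
- from: 0
  to: 1
  R: 0.016064257028
- from: 1
  to: 2
  R: 0.096385542169
- from: 2
  to: 3
  R: 4.473601007227
  valve: microvascular
  reflex_resistance: yes
- from: 3
  to: 4
  R: 0.176706827309
- from: 4
  to: 15
  R: 0.044979919679
- from: 0
  to: 5
  R: 0.017670682731
- from: 5
  to: 6
  R: 0.016064257028
- from: 6
  to: 7
  R: 0.160642570281
- from: 7
  to: 8
  R: 3.743217169312
  valve: microvascular
  reflex_resistance: yes
- from: 8
  to: 13
  R: 0.176706827309
- from: 6
  to: 9
  R: 0.112449799197
- from: 9
  to: 10
  R: 2.73893939218
  valve: microvascular
  reflex_resistance: yes
- from: 10
  to: 13
  R: 0.112449799197
- from: 6
  to: 11
  R: 0.144578313253
- from: 11
  to: 12
  R: 4.10840908827
  valve: microvascular
  reflex_resistance: yes
- from: 12
  to: 13
  R: 0.160642570281
- from: 13
  to: 14
  R: 0.030522088353
- from: 14
  to: 15
  R: 0.012851405622
- from: 15
  to: 16
  R: 0.008032128514
  valve: cardiac
- from: 16
  to: 17
  R: 0.004819277108
  valve: cardiac
- from: 17
  to: 18
  R: 0.128514056225
- from: 18
  to: 19
  R: 0.016064257028
- from: 19
  to: 20
  R: 0.016064257028
  valve: cardiac
reflex:
  enabled: yes
  window_n: 250
  tick_hz: 200
  setpoints:
    arterial: 53.0
    pulse: 24.1
    venous: 11.0
  limits:
    abr: 18.0
    cpr: 5.0
  arcs:
  - name: abr_hr_para
    source: abp
    class: abr
    delay: 0.1
    peak: 0.5
    end: 1.0
    rate_hz: 200
    g_hr: -0.8
  - name: abr_hr_symp
    source: abp
    class: abr
    delay: 2.0
    peak: 5.0
    end: 30.0
    rate_hz: 20
    g_hr: -0.6
  - name: abr_contract
    source: abp
    class: abr
    delay: 2.0
    peak: 5.0
    end: 30.0
    rate_hz: 20
    g_contract: -0.015
  - name: abr_resist
    source: abp
    class: abr
    delay: 2.0
    peak: 6.0
    end: 40.0
    rate_hz: 20
    g_resist: -0.09
  - name: abr_pp_symp
    source: pp
    class: abr
    delay: 2.0
    peak: 5.0
    end: 30.0
    rate_hz: 20
    g_hr: -0.3
    g_contract: -0.008
  - name: abr_vtone
    source: abp
    class: abr
    delay: 10.0
    peak: 170.0
    end: 290.0
    rate_hz: 10
    g_vu: 26.145
  - name: cpr_resist
    source: cvp
    class: cpr
    delay: 5.0
    peak: 30.0
    end: 60.0
    rate_hz: 20
    g_resist: -0.04
  - name: cpr_vtone
    source: cvp
    class: cpr
    delay: 300.0
    peak: 480.0
    end: 620.0
    rate_hz: 10
    g_vu: 105.2025
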