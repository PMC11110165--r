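parameters:
- name: alkyne
  kind: categorical
  options:
  - 2-ethynyltoluene
  - 4-ethynyltoluene
  - 1-chloro-2-ethynylbenzene
  - 1-chloro-4-ethynylbenzene
- name: chloramine_eq
  kind: ordinal-numeric
  options:
  - 0.0
  - 1.0
  - 1.5
  - 2.0
- name: solvent
  kind: categorical
  options:
  - MeOH
  - CH3CN/H2O
  - THF
  - DMF
  - DMSO
  - DCM
  - EtOAc
  - 1,4-dioxane
  - MTBE
  - DCE
- name: iodine_source
  kind: categorical
  options:
  - KI
  - NaI
  - TBAI
  - NH4I
  - NIS
- name: iodine_source_eq
  kind: ordinal-numeric
  options:
  - 0.0
  - 1.0
  - 1.5
  - 2.0
- name: catalyst
  kind: categorical
  options:
  - PTSA
  - AcOH
  - none
- name: catalyst_eq
  kind: ordinal-numeric
  options:
  - 0.0
  - 0.1
  - 1.0
- name: temperature
  kind: ordinal-numeric
  options:
  - 25.0
  - 35.0
  - 45.0
  - 55.0
  - 65.0
  - 75.0
  - 85.0
  - 95.0
constraints:
- rule_id: bp-cap
  rule_kind: max-temperature-by-solvent
  payload:
    field: temperature
    solvent_field: solvent
    limits:
      MeOH: 64.7
      CH3CN: 81.6
      CH3CN/H2O: 100.0
      THF: 66.0
      DMF: 153.0
      DMSO: 189.0
      DCM: 39.6
      EtOAc: 77.1
      1,4-dioxane: 101.3
      MTBE: 55.2
      DCE: 83.5
- rule_id: no-NIS-with-chloramine
  rule_kind: forbidden-combination
  payload:
    field_a: iodine_source
    values_a:
    - NIS
    field_b: chloramine_eq
    values_b:
    - 1.0
    - 1.5
    - 2.0
- rule_id: no-acid-catalyst-with-chloramine
  rule_kind: forbidden-combination
  payload:
    field_a: catalyst
    values_a:
    - PTSA
    - AcOH
    field_b: chloramine_eq
    values_b:
    - 1.0
    - 1.5
    - 2.0
- rule_id: chloramine-at-least-stoichiometric
  rule_kind: min-equivalents-when-active
  payload:
    active_field: iodine_source
    active_values:
    - KI
    - NaI
    - TBAI
    - NH4I
    eq_field: chloramine_eq
    min: 1.0
- rule_id: iodine-source-at-least-stoichiometric
  rule_kind: min-equivalents-when-active
  payload:
    active_field: iodine_source
    active_values:
    - KI
    - NaI
    - TBAI
    - NH4I
    - NIS
    eq_field: iodine_source_eq
    min: 1.0
- rule_id: no-catalyst-means-zero-eq
  rule_kind: conditional-requirement
  payload:
    if_field: catalyst
    if_values:
    - none
    then_field: catalyst_eq
    then_values:
    - 0.0
- rule_id: catalyst-needs-nonzero-eq
  rule_kind: conditional-requirement
  payload:
    if_field: catalyst
    if_values:
    - PTSA
    - AcOH
    then_field: catalyst_eq
    then_values:
    - 0.1
    - 1.0
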