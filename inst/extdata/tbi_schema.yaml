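# Default clinical-variable schema: 37 variables available at the initial
# ED evaluation of mild (GCS 13-15) closed-head-injury patients.
# vtype: binary (codes 0/1), ordinal (codes 1..L), numeric (integer range).
# bins: cut points for raw-vital -> ordinal conversion; upper_open: TRUE when
# the top band is "greater than" its cut point (cut point belongs to the
# middle band), FALSE when it is "at least" (cut point belongs to the top band).
- name: age
  category: demographics
  vtype: ordinal
  levels: [1, 2, 3]
  labels: ["<30", "30-45", ">45"]
- name: gender
  category: demographics
  vtype: binary
  levels: [0, 1]
  labels: [female, male]
- name: ethnicity
  category: demographics
  vtype: binary
  levels: [0, 1]
  labels: [not hispanic or latino, hispanic or latino]
- name: education
  category: demographics
  vtype: binary
  levels: [0, 1]
  labels: [college and grad, before high and high]
- name: employment
  category: demographics
  vtype: binary
  levels: [0, 1]
  labels: [employed, unemployed]
- name: marital_status
  category: demographics
  vtype: binary
  levels: [0, 1]
  labels: [married, not married]
- name: alcohol_use
  category: medical_history
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: prior_developmental_disease
  category: medical_history
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: prior_psychiatric_disease
  category: medical_history
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: mech_bike
  category: mechanism
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: mech_pedestrian
  category: mechanism
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: mech_motorcycle
  category: mechanism
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: mech_motor
  category: mechanism
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: mech_other_person
  category: mechanism
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: mech_fall
  category: mechanism
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: mech_striking
  category: mechanism
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: mech_other
  category: mechanism
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: gcs_ed_arrival
  category: ed_exam
  vtype: numeric
  range: [13, 15]
- name: gcs_assessment_condition
  category: ed_exam
  vtype: binary
  levels: [0, 1]
  labels: [no sedation or paralysis, sedation or paralysis]
- name: gcs_ed_discharge
  category: ed_exam
  vtype: numeric
  range: [3, 15]
- name: hospital_type
  category: ed_exam
  vtype: binary
  levels: [0, 1]
  labels: [primary, secondary]
- name: pta_duration
  category: ed_exam
  vtype: ordinal
  levels: [1, 2, 3]
  labels: [none, "<1 min", ">=1 min"]
- name: ct_result
  category: ed_exam
  vtype: binary
  levels: [0, 1]
  labels: [without abnormality, abnormal]
- name: pupil_reactivity
  category: ed_exam
  vtype: ordinal
  levels: [1, 2, 3]
  labels: [both reactive, one reactive, neither reactive]
- name: alcohol_intoxication
  category: blood_work
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: drug_intoxication
  category: blood_work
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: dbp_ed
  category: vital_signs
  vtype: ordinal
  levels: [1, 2, 3]
  labels: [low, normal, high]
  bins: [60, 90]
  upper_open: false
  units: mm Hg
- name: sbp_ed
  category: vital_signs
  vtype: ordinal
  levels: [1, 2, 3]
  labels: [low, normal, high]
  bins: [90, 140]
  upper_open: false
  units: mm Hg
- name: heart_rate_ed
  category: vital_signs
  vtype: ordinal
  levels: [1, 2, 3]
  labels: [low, normal, high]
  bins: [60, 101]
  upper_open: false
  units: bpm
- name: temperature_ed
  category: vital_signs
  vtype: ordinal
  levels: [1, 2, 3]
  labels: [low, normal, high]
  bins: [35, 37.7]
  upper_open: true
  units: degrees Celsius
- name: o2_saturation_ed
  category: vital_signs
  vtype: ordinal
  levels: [1, 2]
  labels: [low, normal]
  bins: [90]
  upper_open: false
  units: percent
- name: respiratory_rate_ed
  category: vital_signs
  vtype: ordinal
  levels: [1, 2, 3]
  labels: [low, normal, high]
  bins: [12, 21]
  upper_open: false
  units: breaths/min
- name: blood_transfusion
  category: complications
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: hypotension
  category: complications
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: hypoxia
  category: complications
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: intubation
  category: complications
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
- name: seizure
  category: complications
  vtype: binary
  levels: [0, 1]
  labels: [no, yes]
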