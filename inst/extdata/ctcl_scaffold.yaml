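# Worked example: prognosis of early-stage cutaneous T cell lymphoma (CTCL).
schema_version: 1
step1_clinical_scenario: >
  Prognosis of cutaneous T cell lymphoma (CTCL). Early-stage patients
  (Stages IA-IIA) usually do well with slowly progressive disease, but
  about 15% have an unexpectedly rapid progressive course.
step2_principal_goal: >
  Identify, among patients diagnosed with early-stage CTCL, who should
  receive aggressive therapy immediately.
step3_clinical_benefit: >
  A progression-risk classifier separating high- and low-risk patients
  would enable personalised, more aggressive upfront therapy for the
  patients at highest risk of progression.
step4_discomfort_range:
  nnt_lower: 2
  nnt_upper: 30
step5_prospective:
  n_total: 40
  positive_fraction: 0.25
  nnt_pos: 2
  nnt_neg: 30
  followup_note: >
    Recruitment over 3 years with a minimum of 2 years follow-up.
step6_retrospective:
  n_cases: 22
  n_controls: 40
  sn_successes: 18
  sp_successes: 34
  prevalence: 0.15
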