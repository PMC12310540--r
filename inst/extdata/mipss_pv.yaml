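# MIPSS-PV comparator score configuration (clinical-molecular).
# NOTE: component weights follow the published mutation-enhanced score for
# PV; VERIFY AGAINST THE CITED SOURCE before clinical or benchmarking use.
# Requires a derived field `srsf2_mutated` (0/1) and `prior_thrombosis`
# (0/1, any arterial or venous history) on the patient table.
name: MIPSS-PV
criteria:
  - {field: srsf2_mutated, op: eq, value: 1, points: 3}
  - {field: age_dx, op: gt, value: 67, points: 2}
  - {field: leukocytes, op: ge, value: 15, points: 1}
  - {field: prior_thrombosis, op: eq, value: 1, points: 1}
categories:
  cutpoints: [1, 3]
  labels: [low, intermediate, high]
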