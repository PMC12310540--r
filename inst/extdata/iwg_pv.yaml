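# IWG-PV comparator survival score configuration.
# NOTE: component weights follow the originally published IWG score for PV;
# VERIFY AGAINST THE CITED SOURCE before clinical or benchmarking use.
# Age contributes cumulatively: >=57 years adds 2 points and >=67 years adds
# a further 3 (total 5 at >=67).
name: IWG-PV
criteria:
  - {field: age_dx, op: ge, value: 57, points: 2}
  - {field: age_dx, op: ge, value: 67, points: 3}
  - {field: leukocytes, op: ge, value: 15, points: 1}
  - {field: prior_venous_thrombosis, op: eq, value: 1, points: 1}
categories:
  cutpoints: [1, 3]
  labels: [low, intermediate, high]
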