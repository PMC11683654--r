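Relation types:
- produces: a disease and a sign or symptom produced by that disease.
- increases_risk_of: the presence of one disease increases the likelihood
  of the presence of another disorder.
- is_a: a disease and its classification as a more general disease.
- is_acron: an acronym and its full or expanded form.
- is_synon: two different names designating the same disease.
- anaphora: an antecedent and an anaphor entity; the antecedent must be a
  rare disease.
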