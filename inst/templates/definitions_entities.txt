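Entity types:
- rare_disease: a disease that affects a small number of people compared
  with the general population, commonly fewer than 1 in 2000 individuals.
- disease: an abnormal condition of a part, organ, or system of an organism,
  characterized by a patterned group of signs or symptoms.
- symptom_and_sign: an abnormality that may suggest a disease; a symptom is
  a subjective finding reported by the patient, a sign is an observable or
  otherwise discoverable abnormal feature.
- anaphor: a pronoun, word, or nominal phrase that refers to a rare disease
  mentioned earlier (the antecedent of the anaphor).
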