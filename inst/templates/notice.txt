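Notice:
- Extract mentions exactly as they appear in the passage; do not paraphrase
  or expand abbreviations.
- A term flagged as negated is asserted to be absent; never report it as a
  present finding.
- Do not classify common, well-known diseases as rare_disease unless the
  rare-disease knowledge confirms it.
- A mention may occur several times; report every occurrence.
- Only report relations the passage itself asserts, not relations you know
  from background medicine.
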