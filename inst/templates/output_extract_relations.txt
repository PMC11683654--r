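Answer with a single JSON object and nothing else, in this exact shape:
{"relations": [{"subject": "<entity name>", "type": "produces|increases_risk_of|is_a|is_acron|is_synon|anaphora", "object": "<entity name>"}, ...]}
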