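Answer with a single JSON object and nothing else, in this exact shape:
{"entities": [{"name": "<surface form>", "type": "rare_disease|disease|symptom_and_sign|anaphor"}, ...]}
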