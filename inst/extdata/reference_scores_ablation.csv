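method,entity_f1,relation_f1,overall_f1
OntologyEnhanced,56.1,38.6,47.3
without_knowledge,53.8,36.1,45.0
without_exemplars,52.9,34.9,43.9
without_notice,44.7,33.7,39.2
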