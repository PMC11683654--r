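method,task,type,precision,recall,f1
BioClinicalBERT,entity,rare_disease,80.5,87.7,83.9
BioClinicalBERT,entity,disease,53.2,46.0,49.3
BioClinicalBERT,entity,symptom_and_sign,62.3,62.5,62.4
BioClinicalBERT,entity,anaphor,89.9,93.7,91.7
BioClinicalBERT,entity,entity_overall,70.9,72.0,71.4
BioClinicalBERT,relation,produces,49.7,13.6,21.4
BioClinicalBERT,relation,increases_risk_of,0.0,0.0,0.0
BioClinicalBERT,relation,is_a,80.0,4.3,8.1
BioClinicalBERT,relation,is_acron,0.0,0.0,0.0
BioClinicalBERT,relation,is_synon,0.0,0.0,0.0
BioClinicalBERT,relation,anaphora,82.9,23.3,36.3
BioClinicalBERT,relation,relation_overall,57.0,13.4,21.7
BioClinicalBERT,overall,overall,64.0,42.7,46.5
BaseLLM,entity,rare_disease,94.8,38.4,54.7
BaseLLM,entity,disease,22.5,59.8,32.7
BaseLLM,entity,symptom_and_sign,48.7,41.7,44.9
BaseLLM,entity,anaphor,45.2,69.5,54.7
BaseLLM,entity,entity_overall,43.2,46.3,44.7
BaseLLM,relation,produces,26.5,3.3,5.8
BaseLLM,relation,increases_risk_of,9.6,8.1,8.8
BaseLLM,relation,is_a,33.0,30.9,31.9
BaseLLM,relation,is_acron,17.1,21.8,19.2
BaseLLM,relation,is_synon,0.0,0.0,0.0
BaseLLM,relation,anaphora,41.7,55.3,47.6
BaseLLM,relation,relation_overall,32.5,15.6,21.1
BaseLLM,overall,overall,37.9,30.9,32.9
OntologyEnhanced,entity,rare_disease,93.1,75.6,83.5
OntologyEnhanced,entity,disease,26.6,54.9,35.8
OntologyEnhanced,entity,symptom_and_sign,45.8,46.5,46.1
OntologyEnhanced,entity,anaphor,59.0,79.0,67.5
OntologyEnhanced,entity,entity_overall,51.8,61.1,56.1
OntologyEnhanced,relation,produces,37.2,32.4,34.7
OntologyEnhanced,relation,increases_risk_of,11.8,13.1,12.4
OntologyEnhanced,relation,is_a,41.4,34.0,37.4
OntologyEnhanced,relation,is_acron,49.2,40.0,44.1
OntologyEnhanced,relation,is_synon,12.8,22.7,16.3
OntologyEnhanced,relation,anaphora,52.4,63.7,57.5
OntologyEnhanced,relation,relation_overall,39.8,37.5,38.6
OntologyEnhanced,overall,overall,45.8,49.3,47.3
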