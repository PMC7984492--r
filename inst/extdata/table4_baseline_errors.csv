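step,percent_detectable
PatientAssessment,7.7
Simulation,28.2
TreatmentPlanning,49.2
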