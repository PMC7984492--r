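"item_id","source","category","description","rpn","use_frequency","recommended","class_tg275","class_umms_tool","class_umms_exp"
"T315-01","TG315","PatientAssessment","TG-315 skeleton item 01 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-02","TG315","PatientAssessment","TG-315 skeleton item 02 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-03","TG315","PatientAssessment","TG-315 skeleton item 03 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-04","TG315","PatientAssessment","TG-315 skeleton item 04 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-05","TG315","PatientAssessment","TG-315 skeleton item 05 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-06","TG315","PatientAssessment","TG-315 skeleton item 06 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-07","TG315","PatientAssessment","TG-315 skeleton item 07 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-08","TG315","PatientAssessment","TG-315 skeleton item 08 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-09","TG315","Simulation","TG-315 skeleton item 09 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-10","TG315","Simulation","TG-315 skeleton item 10 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-11","TG315","Simulation","TG-315 skeleton item 11 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-12","TG315","Simulation","TG-315 skeleton item 12 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-13","TG315","Simulation","TG-315 skeleton item 13 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-14","TG315","Simulation","TG-315 skeleton item 14 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-15","TG315","Simulation","TG-315 skeleton item 15 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-16","TG315","Simulation","TG-315 skeleton item 16 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-17","TG315","Simulation","TG-315 skeleton item 17 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-18","TG315","Simulation","TG-315 skeleton item 18 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-19","TG315","Simulation","TG-315 skeleton item 19 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-20","TG315","Simulation","TG-315 skeleton item 20 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-21","TG315","TreatmentPlanning","TG-315 skeleton item 21 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-22","TG315","TreatmentPlanning","TG-315 skeleton item 22 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-23","TG315","TreatmentPlanning","TG-315 skeleton item 23 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-24","TG315","TreatmentPlanning","TG-315 skeleton item 24 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-25","TG315","TreatmentPlanning","TG-315 skeleton item 25 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-26","TG315","TreatmentPlanning","TG-315 skeleton item 26 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-27","TG315","TreatmentPlanning","TG-315 skeleton item 27 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-28","TG315","TreatmentPlanning","TG-315 skeleton item 28 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-29","TG315","TreatmentPlanning","TG-315 skeleton item 29 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-30","TG315","TreatmentPlanning","TG-315 skeleton item 30 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-31","TG315","TreatmentPlanning","TG-315 skeleton item 31 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-32","TG315","TreatmentPlanning","TG-315 skeleton item 32 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-33","TG315","TreatmentPlanning","TG-315 skeleton item 33 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-34","TG315","TreatmentPlanning","TG-315 skeleton item 34 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-35","TG315","TreatmentPlanning","TG-315 skeleton item 35 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-36","TG315","TreatmentPlanning","TG-315 skeleton item 36 (placeholder text; published item wording not reproduced)","","","TRUE","","",""
"T315-37","TG315","TreatmentPlanning","TG-315 skeleton item 37 (placeholder text; published item wording not reproduced)","","","FALSE","","",""
"T315-38","TG315","TreatmentPlanning","TG-315 skeleton item 38 (placeholder text; published item wording not reproduced)","","","FALSE","","",""
"T315-39","TG315","TreatmentPlanning","TG-315 skeleton item 39 (placeholder text; published item wording not reproduced)","","","FALSE","","",""
"T315-40","TG315","TreatmentPlanning","TG-315 skeleton item 40 (placeholder text; published item wording not reproduced)","","","FALSE","","",""
"T315-41","TG315","TreatmentPlanning","TG-315 skeleton item 41 (placeholder text; published item wording not reproduced)","","","FALSE","","",""
"T315-42","TG315","TreatmentPlanning","TG-315 skeleton item 42 (placeholder text; published item wording not reproduced)","","","FALSE","","",""
"T315-43","TG315","TreatmentPlanning","TG-315 skeleton item 43 (placeholder text; published item wording not reproduced)","","","FALSE","","",""
"T315-44","TG315","TreatmentPlanning","TG-315 skeleton item 44 (placeholder text; published item wording not reproduced)","","","FALSE","","",""
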