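item_id,source,category,description,rpn,use_frequency,recommended,class_tg275,class_umms_tool,class_umms_exp
PA-01,TG275,PatientAssessment,"Prescription (with respect to standard of care or institutional clinical guidelines)",,,,No,,Full
PA-02,TG275,PatientAssessment,"Diagnosis definition, including imaging and outside records",,,,No,,Full/Partial
PA-03,TG275,PatientAssessment,"Pathology report",,,,No,,Partial
PA-04,TG275,PatientAssessment,"Medical chart to confirm laterality, site, etc.",,,,No,,Full/Partial
PA-05,TG275,PatientAssessment,"Special considerations for radiotherapy (e.g., pacemakers, ICDs, pumps, etc.)",,,,Partial,,Full
PA-06,TG275,PatientAssessment,"Previous radiotherapy treatments",,,,Partial,,Full/Partial
PA-07,TG275,PatientAssessment,"Utilization of other treatment modalities (i.e., chemotherapy, surgery)",,,,No,,Full/Partial
PA-08,TG275,PatientAssessment,"Patient consent",,,,Partial,,Full/Partial
PA-09,TG275,PatientAssessment,"Peer review of treatment decision (e.g., tumor board, peer-to-peer evaluation, etc.)",,,,Partial,,Full
PA-10,TG275,PatientAssessment,"Consult note",,,,Partial,,Full/Partial
PA-11,TG275,PatientAssessment,"Insurance approval",,,,Partial,,Full
SIM-01,TG275,Simulation,"Physician directive for imaging technique, setup and immobilization (may include contrast, scanning orientation, immobilization device, etc.)",,,,Partial,,Full
SIM-02,TG275,Simulation,"Description of target location on physician planning directive (e.g., RUL Lung, H&N, L1-L4)",,,,Partial,,Full
SIM-03,TG275,Simulation,"Utilization of immobilization and ancillary devices",,,,No,,Full
SIM-04,TG275,Simulation,"Construction of immobilization and ancillary devices",,,,No,,No
SIM-05,TG275,Simulation,"Written or photographic documentation of patient positioning, immobilization, and ancillary devices",,,,Partial,,Full
SIM-06,TG275,Simulation,"Isocenter placement",,,,No,,Full/Partial
SIM-07,TG275,Simulation,"Isocenter consistency between patient marking and setup instructions",,,,Partial,,Full
SIM-08,TG275,Simulation,"Patient setup and positioning",,,,Partial,,Partial
SIM-09,TG275,Simulation,"Setup note",,,,No,,Full/Partial
SIM-10,TG275,Simulation,"CT scanner technique (e.g., kV, filter, etc.)",,,,No,,Full
SIM-11,TG275,Simulation,"CT scan artifacts",,,,No,,Partial
SIM-12,TG275,Simulation,"CT scanning range (i.e., superior-inferior range includes entire target and organs at risk)",,,,No,,Full/Partial
SIM-13,TG275,Simulation,"CT scan field of view and clipping of anatomy",,,,No,,Full/Partial
SIM-14,TG275,Simulation,"Use of contrast and corresponding effects on HU number",,,,No,,Partial
SIM-15,TG275,Simulation,"4D CT parameters and data set",,,,No,,Full
SIM-16,TG275,Simulation,"Breath-hold parameters and dataset",,,,No,,Partial
SIM-17,TG275,Simulation,"Gating parameters",,,,No,,Partial
TP-01,TG275,TreatmentPlanning,"Contour check: target(s)",,,,Partial,,Full
TP-02,TG275,TreatmentPlanning,"Contour check: organs at risk",,,,Partial,,Full/Partial
TP-03,TG275,TreatmentPlanning,"Contour check: body/external contour (if required/applicable)",,,,Partial,,Full/Partial
TP-04,TG275,TreatmentPlanning,"Contour check: high-Z material, contrast, artifacts",,,,No,,Full/Partial
TP-05,TG275,TreatmentPlanning,"Prescription check: additional shielding",,,,No,,No
TP-06,TG275,TreatmentPlanning,"Prescription check: prescription vs consult note",,,,No,,Full
TP-07,TG275,TreatmentPlanning,"Dose distribution and overall quality of the plan: dose distribution",,,,No,,Full
TP-08,TG275,TreatmentPlanning,"Dose distribution and overall quality of the plan: prior radiation",,,,Partial,,Full
TP-09,TG275,TreatmentPlanning,"Dose distribution and overall quality of the plan: plan sum (e.g., original plus boost plans)",,,,No,,Full
TP-10,TG275,TreatmentPlanning,"Standard operating procedures followed: setup note",,,,Partial,,Full
TP-11,TG275,TreatmentPlanning,"Standard operating procedures followed: field aperture",,,,No,,Full
TP-12,TG275,TreatmentPlanning,"Standard operating procedures followed: setup shifts",,,,No,,Full
TP-13,TG275,TreatmentPlanning,"Standard operating procedures followed: treatment plan warnings/errors",,,,Partial,,Full/Partial
TP-14,TG275,TreatmentPlanning,"Data transfer from TPS to a third-party OIS: couch parameters",,,,Partial,,Full
TP-15,TG275,TreatmentPlanning,"Data transfer from TPS to a third-party OIS: setup note",,,,Partial,,Full
TP-16,TG275,TreatmentPlanning,"Data transfer from TPS to a third-party OIS: imaging sequence",,,,Partial,,Full
TP-17,TG275,TreatmentPlanning,"Image guidance setup: matching instructions (e.g., 2D/2D, 3D, etc.)",,,,No,,Full
TP-18,TG275,TreatmentPlanning,"Image guidance setup: imaging technique",,,,No,,Full
TP-19,TG275,TreatmentPlanning,"Image guidance setup: DRR image quality",,,,No,,Full
TP-20,TG275,TreatmentPlanning,"Image guidance setup: matching structures",,,,Partial,,Full
TP-21,TG275,TreatmentPlanning,"Plan validity on new simulation CT: old/new CT registration",,,,No,,Full
TP-22,TG275,TreatmentPlanning,"Plan validity on new simulation CT: isocenter placement",,,,No,,Full
TP-23,TG275,TreatmentPlanning,"Plan validity on new simulation CT: deformed or new contours",,,,No,,Full
TP-24,TG275,TreatmentPlanning,"Other initial plan checks: registration/fusion of image sets (CT, PET, MRI, etc.)",,,,No,,Full/Partial
TP-25,TG275,TreatmentPlanning,"Other initial plan checks: image set chosen for treatment planning",,,,No,,Full
TP-26,TG275,TreatmentPlanning,"Other initial plan checks: physician-designed apertures",,,,No,,Full/Partial
TP-27,TG275,TreatmentPlanning,"Other initial plan checks: physics consult (e.g., dose to pacemaker, previous treatment, etc.)",,,,No,,Full
TP-28,TG275,TreatmentPlanning,"Other initial plan checks: parameters and setup for specialized devices (e.g., surface imaging, respiratory monitoring)",,,,No,,Full
TP-29,TG275,TreatmentPlanning,"Other initial plan checks: request for in vivo dosimetry",,,,Partial,,Full
TP-30,TG275,TreatmentPlanning,"Other initial plan checks: motion management instructions",,,,Partial,,Full/Partial
TP-31,TG275,TreatmentPlanning,"Other initial plan checks: instruction for replanning",,,,No,,Full
TP-32,TG275,TreatmentPlanning,"Other initial plan checks: scheduling of tasks (e.g., weekly chart checks, MD image review, etc.)",,,,No,,Full
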