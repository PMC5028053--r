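chf	congestive heart failure
3vd	three vessel disease
lvh	left ventricular hypertrophy
htn	hypertension
dm	diabetes mellitus
mi	myocardial infarction
mi	mitral incompetence
sob	shortness of breath
cad	coronary artery disease
ckd	chronic kidney disease
copd	chronic obstructive pulmonary disease
afib	atrial fibrillation
dvt	deep venous thrombosis
jvp	jugular venous pressure
pcwp	pulmonary capillary wedge pressure
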