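concept_id	semantic_type	synonym
C0001	T047	left ventricular hypertrophy
C0002	T184	chest pain increasing in severity
C0003	T047	left anterior descending coronary artery stenosis
C0004	T033	raised jugular venous pressure
C0004	T033	elevated jugular venous pressure
C0005	T033	jugular venous pressure
C0006	T033	pulmonary capillary wedge pressure increased
C0007	T033	pulmonary capillary wedge pressure decreased
C0008	T047	diabetes mellitus
C0010	T047	chronic leg ulcer
C0011	T033	leg edema
C0012	T033	increased insulin requirement
C0013	T047	hypoxia
C0013	T047	oxygen deficiency
C0014	T047	moderate left ventricular systolic dysfunction
C0015	T033	moderately or severely depressed left ventricular systolic function
C0016	T047	high blood pressure
C0017	T033	blood pressure
C0018	T047	congestive heart failure
C0019	T047	three vessel disease
C0020	T191	breast neoplasms
C0020	T191	breast cancer
C0021	T191	brain neoplasms
C0021	T191	brain cancer
C0022	T191	prostatic neoplasms
C0022	T191	prostate cancer
C0023	T191	kidney neoplasms
C0023	T191	kidney cancer
C0024	T191	breast and ovarian cancer syndrome
C0025	T191	ovarian neoplasms
C0025	T191	ovarian cancer
C0026	T191	neoplasms
C0027	T047	left ventricular dilatation
C0028	T033	left ventricular enlargement
C0029	T047	right ventricular hypertrophy
C0030	T184	chest pain
C0031	T184	atypical chest pain
C0032	T184	chest wall pain
C0033	T047	coronary artery disease
C0034	T047	coronary artery stenosis
C0035	T047	renal artery stenosis
C0036	T047	aortic stenosis
C0037	T047	mitral valve stenosis
C0038	T047	mitral regurgitation
C0039	T047	pulmonary embolism
C0040	T047	pulmonary hypertension
C0041	T047	pulmonary edema
C0042	T047	deep venous thrombosis
C0043	T047	gestational diabetes mellitus
C0044	T047	diabetes insipidus
C0045	T033	insulin resistance
C0046	T184	leg pain
C0047	T047	chronic kidney disease
C0048	T047	chronic obstructive pulmonary disease
C0049	T184	fatigue
C0050	T047	hypertension
C0051	T047	unstable angina
C0052	T047	stable angina
C0053	T184	dyspnea on exertion
C0054	T047	hyperkalemia
C0055	T033	decreased renal function
C0055	T033	worsening renal function
C0056	T033	left ventricular function
C0056	T033	left ventricular systolic function
C0057	T033	renal function abnormal
C0058	T033	decreased cardiac output
C0059	T047	myocardial infarction
C0060	T033	shortness of breath
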