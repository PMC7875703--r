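flag,phrase
alzheimers,dementia or alzheimer disease
asthma,asthma
cancer,cancer
cerebrovascular,history of cerebrovascular disease or stroke
chf,congestive heart failure
ckd,chronic kidney disease
copd,chronic obstructive pulmonary disease
depression,depression
diabetes,diabetes mellitus
esrd,end stage renal disease on dialysis
hiv,hiv infection
htn,hypertension
hyperlipidemia,hyperlipidemia
mi,history of myocardial infarction
obesity,obesity
osa,obstructive sleep apnea
osteoporosis,osteoporosis
pulmonary_embolism,history of pulmonary embolism
substance_abuse,substance abuse disorder
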