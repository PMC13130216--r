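# Synthetic stand-in for a renal-injury SMQ preferred-term list.
# The licensed MedDRA query (113 PTs covering chronic kidney disease,
# tubulointerstitial disease, acute renal failure, renovascular
# disorders and proteinuria) is a user-supplied input; this fixture
# covers the event PTs emitted by the package's synthetic generator
# plus common renal terms, for tests and examples only.
acute kidney injury
renal impairment
blood creatinine increased
renal failure
proteinuria
glomerular filtration rate decreased
chronic kidney disease
thrombotic microangiopathy
nephropathy toxic
renal tubular necrosis
oliguria
haematuria
renal tubular atrophy
renal vessel disorder
focal segmental glomerulosclerosis
renal tubular injury
urine protein/creatinine ratio increased
urine albumin/creatinine ratio increased
biopsy kidney abnormal
diffuse mesangial sclerosis
renal arteritis
blood urea increased
anuria
nephritis interstitial
renal injury
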