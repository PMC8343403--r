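midazolam
paracetamol
acetaminophen
ibuprofen
warfarin
digoxin
gentamicin
vancomycin
rifampicin
caffeine
theophylline
valproic acid
amoxicillin
ciprofloxacin
metformin
morphine
fentanyl
propofol
ketamine
tacrolimus
cyclosporine
methotrexate
carbamazepine
phenytoin
lamotrigine
voriconazole
fluconazole
meropenem
piperacillin
dexamethasone
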