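##gff-version 3
Q8LAX3	featuretracks	active_peptide	74	96	.	.	.	ID=f1;Note=Elicitor%20peptide%203;type_code=SO:0001064;type_category=Molecule%20processing
Q8LAX3	featuretracks	Metal ion binding	12	12	.	.	.	ID=f2;type_category=Binding%20site
Q8LAX3	featuretracks	Glycosylation	30	30	.	.	.	ID=f3;type_category=PTM
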