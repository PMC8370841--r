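patient_id	rsid	genotype	cyp2d6_copy_number
EX01	rs4244285	G/A	2
EX01	rs3892097	G/G	2
EX01	rs16947	C/T	2
EX01	rs6265	G/A	2
EX01	rs4680	A/A	2
EX01	rs1045642	C/T	2
EX01	rs12248560	C/C	2
EX02	rs4244285	G/G	2
EX02	rs3892097	A/A	2
EX02	rs16947	C/C	2
EX02	rs6265	G/G	2
EX02	rs4680	G/A	2
EX02	rs1045642	T/T	2
EX02	rs12248560	C/T	2
EX03	rs4244285	G/G	2
EX03	rs3892097	G/G	2
EX03	rs16947	C/C	2
EX03	rs6265	G/G	2
EX03	rs4680	G/G	2
EX03	rs1045642	C/C	2
EX03	rs12248560	T/T	2
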