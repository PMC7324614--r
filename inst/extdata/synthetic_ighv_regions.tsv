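gene_id	segment_class	region	start	end
SYNV1	V	FWR2	0	21
SYNV1	V	CDR2	21	36
SYNV1	V	FWR3	36	117
SYNV1	V	CDR3	117	120
SYNV2	V	FWR2	0	21
SYNV2	V	CDR2	21	36
SYNV2	V	FWR3	36	117
SYNV2	V	CDR3	117	120
SYNV3	V	FWR2	0	21
SYNV3	V	CDR2	21	36
SYNV3	V	FWR3	36	117
SYNV3	V	CDR3	117	120
SYNV4	V	FWR2	0	21
SYNV4	V	CDR2	21	36
SYNV4	V	FWR3	36	117
SYNV4	V	CDR3	117	120
SYNJ1	J	CDR3	0	3
SYNJ1	J	FWR4	3	48
SYNJ2	J	CDR3	0	3
SYNJ2	J	FWR4	3	48
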