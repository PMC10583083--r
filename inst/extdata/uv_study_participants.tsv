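participant	skin_type	sex	age	med_uva1_j_cm2	med_uvb_mj_cm2
P1	II	F	24	61.1	37.0
P2	II	F	27	61.1	37.0
P3	I	F	22	48.8	30
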