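etype	original	participle	dedup	percent
tongue_inspection	121709	371760	34144	90.8
pulse_taking	121545	462192	39633	91.5
listening_and_smelling	7972	116435	2899	97.5
inspection	33758	152316	12911	91.5
body_surface_examination	63248	248111	28752	88.4
nursing_precautions	57288	315496	10262	96.7
diagnosis_of_tcm	100038	95543	12102	87.3
syndrome	108746	NA	61916	85.8
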