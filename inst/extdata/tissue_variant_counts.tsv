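organ	total	filtered	significant	moderate	high
Liver	484589	46268	1110	263	6
Muscle	459057	80818	2540	501	25
Hypothalamus	1037253	143540	4586	834	24
Pituitary	846809	125141	3782	847	21
Adrenal	745878	130738	3575	657	10
Unique	2000936	227225	9986	1995	78
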