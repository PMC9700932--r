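organ	missense	affectedGenes
Liver	260	120
Muscle	494	211
Hypothalamus	818	352
Pituitary	823	343
Adrenal	635	286
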