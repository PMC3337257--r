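term_id	label	synonyms	tree_numbers
T01	Heart Diseases		C14
T02	Tricuspid Atresia	Atresia, Tricuspid	C14.280
T03	Heart Septal Defects		C14.281
T04	Anatomy Region		A02
T05	Heart Ventricles	Cardiac Ventricles	A02.100
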