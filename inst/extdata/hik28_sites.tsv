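accession	residue	position	condition
SPLC1_S041070	T	598	LOW
SPLC1_S041070	T	793	LOW
SPLC1_S041070	T	837	LOW
SPLC1_S041070	S	805	LOW
SPLC1_S041070	S	911	LOW
SPLC1_S041070	S	976	LOW
SPLC1_S041070	S	1136	LOW
SPLC1_S041070	S	1482	LOW
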