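# Curated skeleton of a eukaryotic repeat classification tree.
# One node per line; 'path' is the full ';'-joined path from the root.
# Parents precede children. Alias columns map nodes to labels in other
# classification systems where an equivalent exists.
path	repeatmasker	repbase	wicker	curcio_derbyshire
Interspersed_Repeat
Interspersed_Repeat;Unknown	Unknown	Unknown
Interspersed_Repeat;Transposable_Element
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LTR	LTR	LTR	RLX
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LTR;Gypsy	LTR/Gypsy	Gypsy	RLG	Gypsy-like
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LTR;Copia	LTR/Copia	Copia	RLC	Copia-like
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LTR;Bel-Pao	LTR/Pao	BEL	RLB	Bel-like
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LTR;Retrovirus	LTR/ERV	ERV	RLR	Retrovirus
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LTR;Retrovirus;ERV1	LTR/ERV1	ERV1
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LTR;Retrovirus;ERV2	LTR/ERVK	ERV2
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LTR;Retrovirus;ERV3	LTR/ERVL	ERV3
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;DIRS	LTR/DIRS	DIRS	RYD	DIRS-like
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;Penelope	LINE/Penelope	Penelope	RPP	PLE
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE	LINE	Non-LTR	RIX	Target-primed
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE;R2	LINE/R2	R2	RIR
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE;RTE	LINE/RTE	RTE	RIT
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE;Jockey	LINE/Jockey	Jockey	RIJ
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE;Jockey;CR1	LINE/CR1	CR1
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE;I	LINE/I	I	RII
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE;L1	LINE/L1	L1	RIL	L1-group
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE;L1;L1	LINE/L1	L1
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE;L1;Tx1	LINE/Tx1	Tx1
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE-dependent_Retroposon
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE-dependent_Retroposon;SINE	SINE	SINE	RSX
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE-dependent_Retroposon;SINE;tRNA	SINE/tRNA	SINE2	RST
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE-dependent_Retroposon;SINE;7SL	SINE/Alu	SINE1	RSS
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE-dependent_Retroposon;SINE;5S	SINE/5S	SINE3	RSS
Interspersed_Repeat;Transposable_Element;Class_I_Retrotransposition;LINE-dependent_Retroposon;SVA	Retroposon/SVA	SVA
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste	DNA		DTX	DDE
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;hAT	DNA/hAT	hAT	DTA	hAT
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;hAT;Charlie	DNA/hAT-Charlie	Charlie
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;hAT;Tip100	DNA/hAT-Tip100	Tip100
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;Tc1-Mariner	DNA/TcMar	Mariner/Tc1	DTT	Tc1/mariner
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;Tc1-Mariner;Tigger	DNA/TcMar-Tigger	Tigger
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;Mutator	DNA/MULE	MuDR	DTM	Mutator
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;PIF-Harbinger	DNA/PIF-Harbinger	Harbinger	DTH	PIF/Harbinger
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;CACTA	DNA/CMC	EnSpm/CACTA	DTC	CACTA
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;Merlin	DNA/Merlin	Merlin	DTE	Merlin
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;P	DNA/P	P	DTP	P
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;PiggyBac	DNA/PiggyBac	PiggyBac	DTB	PiggyBac
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;Ginger
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;TIR;Transib	DNA/Transib	Transib	DTR	Transib
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Cut-and-Paste;Crypton	DNA/Crypton	Crypton	DYC	Crypton
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Rolling-Circle	RC		DHX	HUH
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Rolling-Circle;Helitron	RC/Helitron	Helitron	DHH	Helitron
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Self-Synthesizing
Interspersed_Repeat;Transposable_Element;Class_II_DNA_Transposition;Self-Synthesizing;Maverick-Polinton	DNA/Maverick	Polinton	DMM	Polinton/Maverick
Interspersed_Repeat;Pseudogene
Interspersed_Repeat;Pseudogene;Retropseudogene	Retroposon
Interspersed_Repeat;Pseudogene;RNA	ncRNA
Interspersed_Repeat;Segmental_Duplication
Tandem_Repeat
Tandem_Repeat;Satellite	Satellite	SAT
Tandem_Repeat;Satellite;Centromeric	Satellite/centr	CEN
Tandem_Repeat;Satellite;Telomeric	Satellite/telo	TEL
Tandem_Repeat;Simple	Simple_repeat
Tandem_Repeat;Low_Complexity	Low_complexity
Accidental_Insertion
Accidental_Insertion;Organelle	Organelle
Accidental_Insertion;Viral
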