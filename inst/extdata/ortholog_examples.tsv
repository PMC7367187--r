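organism	gene	class	phase	sequence
Zea mays		U12-type	0	GCAAAG|GTATCCTTTT…TCCTCCTAAACT…TGCAG|TCCTCC
Oryza sativa		U2-type	0	GCCAAG|GTAATTTATA…TTAATGTTTAAT…TGCAG|TTAATG
Zea mays		U2-type	0	AAGCGG|GTATGTCTAG…TTGATCTCACCT…ATCAG|TTGATC
Glycine max		U12-type	0	AAGCGT|GTATCCTTCA…TTGTCCTTGACC…GAAAG|TTGTCC
Zea mays		U2-type	1	TCAACA|GTACGCAACA…TCCTTCTTAATT…TGTAG|TCCTTC
Oryza sativa		U12-type	1	TCAACA|GTATCCATCA…TTTTTCTTAACT…TGTAG|TTTTTC
Arabidopsis thaliana		U2-type	1	TCAACA|GTAAATTTTC…TTTCTCTTGACC…TGCAG|TTTCTC
Canis familiaris	SMYD2	U12-type	1	ACAAAT|ATATCCTTTA…CTTTCCTTGACA…AGCAC|CTTTCC
Homo sapiens	SMYD2	U12-type	1	ATAAAT|ATATCCTTTA…CTTTCCTTGACT…AGCAC|CTTTCC
Mus musculus	Smyd2	U12-type	1	ACAAAT|ATAACCTTTC…GTTTCCTTGACG…AGCAC|GTTTCC
Macaca mulatta	SMYD2	U2-type	1	ACAACT|GCCCTGATGG…GTTTCCTTGACT…CACAG|GTTTCC
Pan troglodytes	SMYD2	U12-type	1	ATAAAT|ATATCCTTTA…GTTTCCTTGACT…AGCAC|GTTTCC
Rattus norvegicus	Smyd2	U12-type	1	ACAAAT|ATAACCTTTC…GTTTCCTTGACG…AGCAC|GTTTCC
Anopheles gambiae		U2-type	2	TAATCC|GTATGTAACC…TGTTTCTCCTTT…TGTAG|TGTTTC
Monodelphis domestica	RNF121	U12-type	2	TAACCC|GTATCCTTTT…TTTTCTTTAACC…TGAAG|TTTTCT
Rattus norvegicus	Rnf121	U12-type	2	CAATCC|GTATCCTTTG…TGATCCTTAACA…GACAG|TGATCC
Homo sapiens	UFD1	U12-type	2	AGCCGT|GTATCTTTTT…GTTGCCTTGACA…TGCAG|GTTGCC
Pan troglodytes	UFD1	U12-type	2	AGCCGT|GTATCTTTTT…GTTGCCTTGACA…TGCAG|GTTGCC
Tetraodon nigroviridis	ufd1l	U2-type	2	AGCAGT|GTAAGAACGA…GAATTGTTTTCT…TGCAG|GAATTG
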