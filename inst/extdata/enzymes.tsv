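name	site	cut_offset
AatII	GACGTC	5
AccI	GTMKAC	2
AflII	CTTAAG	1
AgeI	ACCGGT	1
AluI	AGCT	2
AlwNI	CAGNNNCTG	6
ApaI	GGGCCC	5
ApoI	RAATTY	1
AscI	GGCGCGCC	2
AseI	ATTAAT	2
AvaI	CYCGRG	1
AvrII	CCTAGG	1
BamHI	GGATCC	1
BbsI	GAAGAC	8
BsaI	GGTCTC	7
BsmBI	CGTCTC	7
BanI	GGYRCC	1
BclI	TGATCA	1
BglI	GCCNNNNNGGC	7
BglII	AGATCT	1
BsiWI	CGTACG	1
BspEI	TCCGGA	1
BsrGI	TGTACA	1
BstBI	TTCGAA	2
BstXI	CCANNNNNNTGG	8
ClaI	ATCGAT	2
DdeI	CTNAG	1
DraI	TTTAAA	3
DraIII	CACNNNGTG	6
EagI	CGGCCG	1
EarI	CTCTTC	7
EcoRI	GAATTC	1
EcoRV	GATATC	3
FokI	GGATG	14
FseI	GGCCGGCC	6
HaeIII	GGCC	2
HincII	GTYRAC	3
HindIII	AAGCTT	1
HinfI	GANTC	1
HpaI	GTTAAC	3
KpnI	GGTACC	5
MboI	GATC	0
MfeI	CAATTG	1
MluI	ACGCGT	1
MseI	TTAA	1
NaeI	GCCGGC	3
NarI	GGCGCC	2
NcoI	CCATGG	1
NdeI	CATATG	2
NheI	GCTAGC	1
NotI	GCGGCCGC	2
NsiI	ATGCAT	5
PacI	TTAATTAA	5
PmeI	GTTTAAAC	4
PstI	CTGCAG	5
PvuI	CGATCG	4
PvuII	CAGCTG	3
RsaI	GTAC	2
SacI	GAGCTC	5
SalI	GTCGAC	1
SapI	GCTCTTC	8
SbfI	CCTGCAGG	6
ScaI	AGTACT	3
SmaI	CCCGGG	3
SnaBI	TACGTA	3
SpeI	ACTAGT	1
SphI	GCATGC	5
StuI	AGGCCT	3
StyI	CCWWGG	1
SwaI	ATTTAAAT	4
TaqI	TCGA	1
XbaI	TCTAGA	1
XhoI	CTCGAG	1
XmnI	GAANNNNTTC	5
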