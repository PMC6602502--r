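class_id	label	color	keys	patterns	enabled
complex_I	complex I (NADH dehydrogenase)	#FFD700		^nad;^nd[0-9]	TRUE
complex_II	complex II (succinate dehydrogenase)	#CD5C5C		^sdh	TRUE
complex_III	complex III (ubiquinol cytochrome c reductase)	#9932CC		^cob$;^cytb$	TRUE
complex_IV	complex IV (cytochrome c oxidase)	#FF7F50		^cox;^co[1-3]$	TRUE
complex_V	ATP synthase	#9ACD32		^atp	TRUE
ccm	cytochrome c biogenesis	#20B2AA		^ccm	TRUE
ribosomal_proteins	ribosomal proteins	#DAA520		^rps;^rpl;^mrp	TRUE
maturase	maturases	#FF8C00		^mat	TRUE
trna	transfer RNAs	#1E90FF	tRNA	^trn	TRUE
rrna	ribosomal RNAs	#B03060	rRNA	^rrn	TRUE
dloop	D-loop / control region	#708090	D-loop;D_loop		TRUE
intron	introns	#FFFFFF	intron		FALSE
operon	polycistronic transcripts	#4682B4	operon;prim_transcript		TRUE
ori	origin of replication	#696969	rep_origin;oriC		TRUE
other	other	#D3D3D3			TRUE
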