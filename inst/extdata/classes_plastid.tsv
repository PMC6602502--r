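class_id	label	color	keys	patterns	enabled
photosystem_I	photosystem I	#2E8B57		^psa;^ycf3$;^ycf4$	TRUE
photosystem_II	photosystem II	#7CC87C		^psb	TRUE
cytochrome_bf	cytochrome b6/f complex	#808000		^pet	TRUE
atp_synthase	ATP synthase	#9ACD32		^atp	TRUE
ndh_dehydrogenase	NADH dehydrogenase	#FFD700		^ndh	TRUE
rubisco	RubisCO large subunit	#6B8E23		^rbc	TRUE
rna_polymerase	RNA polymerase	#B22222		^rpo	TRUE
ribosomal_protein_SSU	ribosomal proteins (SSU)	#DAA520		^rps	TRUE
ribosomal_protein_LSU	ribosomal proteins (LSU)	#CD853F		^rpl	TRUE
clp_mat	clpP, matK	#FF8C00		^clpP$;^matK$	TRUE
other_genes	other genes	#A0A0A0		^ycf;^acc;^ccsA$;^cemA$;^infA$	TRUE
trna	transfer RNAs	#1E90FF	tRNA	^trn	TRUE
rrna	ribosomal RNAs	#B03060	rRNA	^rrn	TRUE
intron	introns	#FFFFFF	intron		FALSE
operon	polycistronic transcripts	#4682B4	operon;prim_transcript		TRUE
ori	origin of replication	#696969	rep_origin;oriC		TRUE
other	other	#D3D3D3			TRUE
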