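class_id	label	color	keys	patterns	enabled
cds	protein-coding genes	#4682B4	CDS		TRUE
trna	transfer RNAs	#1E90FF	tRNA	^trn	TRUE
rrna	ribosomal RNAs	#B03060	rRNA	^rrn	TRUE
intron	introns	#FFFFFF	intron		FALSE
operon	polycistronic transcripts	#6A5ACD	operon;prim_transcript		TRUE
ori	origin of replication	#696969	rep_origin;oriC		TRUE
other	other	#D3D3D3			TRUE
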