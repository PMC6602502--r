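name	category	class_id
psaA	plastid	photosystem_I
psaB	plastid	photosystem_I
psaC	plastid	photosystem_I
psaI	plastid	photosystem_I
psaJ	plastid	photosystem_I
ycf3	plastid	photosystem_I
ycf4	plastid	photosystem_I
psbA	plastid	photosystem_II
psbB	plastid	photosystem_II
psbC	plastid	photosystem_II
psbD	plastid	photosystem_II
psbE	plastid	photosystem_II
psbF	plastid	photosystem_II
psbH	plastid	photosystem_II
psbI	plastid	photosystem_II
psbJ	plastid	photosystem_II
psbK	plastid	photosystem_II
psbL	plastid	photosystem_II
psbM	plastid	photosystem_II
psbN	plastid	photosystem_II
psbT	plastid	photosystem_II
psbZ	plastid	photosystem_II
petA	plastid	cytochrome_bf
petB	plastid	cytochrome_bf
petD	plastid	cytochrome_bf
petG	plastid	cytochrome_bf
petL	plastid	cytochrome_bf
petN	plastid	cytochrome_bf
atpA	plastid	atp_synthase
atpB	plastid	atp_synthase
atpE	plastid	atp_synthase
atpF	plastid	atp_synthase
atpH	plastid	atp_synthase
atpI	plastid	atp_synthase
ndhA	plastid	ndh_dehydrogenase
ndhB	plastid	ndh_dehydrogenase
ndhC	plastid	ndh_dehydrogenase
ndhD	plastid	ndh_dehydrogenase
ndhE	plastid	ndh_dehydrogenase
ndhF	plastid	ndh_dehydrogenase
ndhG	plastid	ndh_dehydrogenase
ndhH	plastid	ndh_dehydrogenase
ndhI	plastid	ndh_dehydrogenase
ndhJ	plastid	ndh_dehydrogenase
ndhK	plastid	ndh_dehydrogenase
rbcL	plastid	rubisco
rpoA	plastid	rna_polymerase
rpoB	plastid	rna_polymerase
rpoC1	plastid	rna_polymerase
rpoC2	plastid	rna_polymerase
rps2	plastid	ribosomal_protein_SSU
rps3	plastid	ribosomal_protein_SSU
rps4	plastid	ribosomal_protein_SSU
rps7	plastid	ribosomal_protein_SSU
rps8	plastid	ribosomal_protein_SSU
rps11	plastid	ribosomal_protein_SSU
rps12	plastid	ribosomal_protein_SSU
rps14	plastid	ribosomal_protein_SSU
rps15	plastid	ribosomal_protein_SSU
rps16	plastid	ribosomal_protein_SSU
rps18	plastid	ribosomal_protein_SSU
rps19	plastid	ribosomal_protein_SSU
rpl2	plastid	ribosomal_protein_LSU
rpl14	plastid	ribosomal_protein_LSU
rpl16	plastid	ribosomal_protein_LSU
rpl20	plastid	ribosomal_protein_LSU
rpl22	plastid	ribosomal_protein_LSU
rpl23	plastid	ribosomal_protein_LSU
rpl32	plastid	ribosomal_protein_LSU
rpl33	plastid	ribosomal_protein_LSU
rpl36	plastid	ribosomal_protein_LSU
clpP	plastid	clp_mat
matK	plastid	clp_mat
accD	plastid	other_genes
ccsA	plastid	other_genes
cemA	plastid	other_genes
infA	plastid	other_genes
ycf1	plastid	other_genes
ycf2	plastid	other_genes
trnH-GUG	plastid	trna
trnK-UUU	plastid	trna
trnQ-UUG	plastid	trna
trnS-GCU	plastid	trna
trnG-UCC	plastid	trna
trnR-UCU	plastid	trna
trnC-GCA	plastid	trna
trnD-GUC	plastid	trna
trnY-GUA	plastid	trna
trnE-UUC	plastid	trna
trnT-GGU	plastid	trna
trnS-UGA	plastid	trna
trnF-GAA	plastid	trna
trnV-UAC	plastid	trna
trnM-CAU	plastid	trna
trnW-CCA	plastid	trna
trnP-UGG	plastid	trna
trnI-CAU	plastid	trna
trnL-CAA	plastid	trna
trnL-UAA	plastid	trna
trnV-GAC	plastid	trna
trnI-GAU	plastid	trna
trnA-UGC	plastid	trna
trnR-ACG	plastid	trna
trnN-GUU	plastid	trna
rrn16	plastid	rrna
rrn23	plastid	rrna
rrn4.5	plastid	rrna
rrn5	plastid	rrna
nad1	mitochondrial	complex_I
nad2	mitochondrial	complex_I
nad3	mitochondrial	complex_I
nad4	mitochondrial	complex_I
nad4L	mitochondrial	complex_I
nad5	mitochondrial	complex_I
nad6	mitochondrial	complex_I
nad7	mitochondrial	complex_I
nad9	mitochondrial	complex_I
sdh3	mitochondrial	complex_II
sdh4	mitochondrial	complex_II
cob	mitochondrial	complex_III
cox1	mitochondrial	complex_IV
cox2	mitochondrial	complex_IV
cox3	mitochondrial	complex_IV
atp1	mitochondrial	complex_V
atp4	mitochondrial	complex_V
atp6	mitochondrial	complex_V
atp8	mitochondrial	complex_V
atp9	mitochondrial	complex_V
ccmB	mitochondrial	ccm
ccmC	mitochondrial	ccm
ccmFc	mitochondrial	ccm
ccmFn	mitochondrial	ccm
rps1	mitochondrial	ribosomal_proteins
rps3	mitochondrial	ribosomal_proteins
rps4	mitochondrial	ribosomal_proteins
rps12	mitochondrial	ribosomal_proteins
rpl5	mitochondrial	ribosomal_proteins
rpl10	mitochondrial	ribosomal_proteins
rpl16	mitochondrial	ribosomal_proteins
matR	mitochondrial	maturase
trnF-GAA	mitochondrial	trna
trnM-CAU	mitochondrial	trna
trnW-CCA	mitochondrial	trna
trnP-UGG	mitochondrial	trna
trnY-GUA	mitochondrial	trna
trnD-GUC	mitochondrial	trna
trnK-UUU	mitochondrial	trna
trnS-UGA	mitochondrial	trna
rrn18	mitochondrial	rrna
rrn26	mitochondrial	rrna
rrn5	mitochondrial	rrna
rrnS	mitochondrial	rrna
rrnL	mitochondrial	rrna
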