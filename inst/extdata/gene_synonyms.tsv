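synonym	canonical
COI	cox1
CO1	cox1
COX1	cox1
COXI	cox1
cytochrome c oxidase subunit I	cox1
cytochrome c oxidase subunit 1	cox1
COII	cox2
CO2	cox2
COX2	cox2
COXII	cox2
cytochrome c oxidase subunit II	cox2
cytochrome c oxidase subunit 2	cox2
COIII	cox3
CO3	cox3
COX3	cox3
COXIII	cox3
cytochrome c oxidase subunit III	cox3
cytochrome c oxidase subunit 3	cox3
CYTB	cob
CYB	cob
COB	cob
cytochrome b	cob
ATP6	atp6
ATPASE6	atp6
ATP synthase F0 subunit 6	atp6
ATP8	atp8
ATPASE8	atp8
ATP synthase F0 subunit 8	atp8
ND1	nad1
NAD1	nad1
NADH dehydrogenase subunit 1	nad1
ND2	nad2
NAD2	nad2
NADH dehydrogenase subunit 2	nad2
ND3	nad3
NAD3	nad3
NADH dehydrogenase subunit 3	nad3
ND4	nad4
NAD4	nad4
NADH dehydrogenase subunit 4	nad4
ND4L	nad4L
NAD4L	nad4L
NADH dehydrogenase subunit 4L	nad4L
ND5	nad5
NAD5	nad5
NADH dehydrogenase subunit 5	nad5
ND6	nad6
NAD6	nad6
NADH dehydrogenase subunit 6	nad6
12S	rrnS
12S ribosomal RNA	rrnS
s-rRNA	rrnS
small subunit ribosomal RNA	rrnS
rrn12	rrnS
SSU	rrnS
16S	rrnL
16S ribosomal RNA	rrnL
l-rRNA	rrnL
large subunit ribosomal RNA	rrnL
rrn16	rrnL
LSU	rrnL
tRNA-Ala	trnA
trnA-ugc	trnA
tRNA-Cys	trnC
trnC-gca	trnC
tRNA-Asp	trnD
trnD-guc	trnD
tRNA-Glu	trnE
trnE-uuc	trnE
tRNA-Phe	trnF
trnF-gaa	trnF
tRNA-Gly	trnG
trnG-ucc	trnG
tRNA-His	trnH
trnH-gug	trnH
tRNA-Ile	trnI
trnI-gau	trnI
tRNA-Lys	trnK
trnK-uuu	trnK
tRNA-Leu	trnL?
trnL	trnL?
tRNA-Leu(CUN)	trnL1
tRNA-Leu(UUR)	trnL2
trnL-uag	trnL1
trnL-uaa	trnL2
tRNA-Met	trnM
trnM-cau	trnM
tRNA-Asn	trnN
trnN-guu	trnN
tRNA-Pro	trnP
trnP-ugg	trnP
tRNA-Gln	trnQ
trnQ-uug	trnQ
tRNA-Arg	trnR
trnR-ucg	trnR
tRNA-Ser	trnS?
trnS	trnS?
tRNA-Ser(AGN)	trnS1
tRNA-Ser(UCN)	trnS2
trnS-gcu	trnS1
trnS-uga	trnS2
tRNA-Thr	trnT
trnT-ugu	trnT
tRNA-Val	trnV
trnV-uac	trnV
tRNA-Trp	trnW
trnW-uca	trnW
tRNA-Tyr	trnY
trnY-gua	trnY
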