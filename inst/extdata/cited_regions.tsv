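accession	start	end	species	note
AB597304.1	1429	1179	Ostrinia nubilalis	reverse-coordinate citation; spans 251 bp
EF396411.1	685	943	Ostrinia nubilalis	forward span, 259 bp
AP009003.1	89798	90133	Bombyx mori	forward span, 336 bp
AP009031.1	54931	54604	Bombyx mori	reverse-coordinate citation; spans 328 bp
ET217030.1	29	273	Ostrinia nubilalis	MITE01 span described as 239 bp although the cited interval covers 245 bp; both numbers recorded verbatim, neither corrected
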