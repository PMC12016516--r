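bait	prey	sulfur	pyruvate	rank	rescued	prey_annotation
TK1130	TK0574	TRUE	TRUE	5	FALSE	metallophosphoesterase, calcineurin superfamily
TK1130	TK0789	TRUE	TRUE	5	FALSE	glycerol-1-phosphate dehydrogenase [NAD(P)+]
TK1130	TK0930	TRUE	TRUE	5	FALSE	uncharacterized protein
TK1130	TK0953	TRUE	TRUE	5	FALSE	predicted ATPase, AAA superfamily, PIN and KH domains
TK1130	TK1328	TRUE	TRUE	5	FALSE	tRNA (1-methyladenosine) methyltransferase
TK1130	TK2012	TRUE	TRUE	5	FALSE	ferredoxin 3
TK1130	TK2093	TRUE	TRUE	5	FALSE	membrane-bound hydrogenase, [4Fe-4S] cluster-binding subunit, MBH-N
TK1130	TK2106	TRUE	TRUE	5	FALSE	enolase
TK1130	TK1131	TRUE	TRUE	4	FALSE	2-oxoacid:ferredoxin oxidoreductase, delta subunit
TK1215	TK0574	TRUE	TRUE	5	FALSE	metallophosphoesterase, calcineurin superfamily
TK1215	TK0789	TRUE	TRUE	5	FALSE	glycerol-1-phosphate dehydrogenase [NAD(P)+]
TK1215	TK0930	TRUE	TRUE	5	FALSE	uncharacterized protein
TK1215	TK0953	TRUE	TRUE	5	FALSE	predicted ATPase, AAA superfamily, PIN and KH domains
TK1215	TK1328	TRUE	TRUE	5	FALSE	tRNA (1-methyladenosine) methyltransferase
TK1215	TK2012	TRUE	TRUE	5	FALSE	ferredoxin 3
TK1215	TK2093	TRUE	TRUE	5	FALSE	membrane-bound hydrogenase, [4Fe-4S] cluster-binding subunit, MBH-N
TK1215	TK2106	TRUE	TRUE	5	FALSE	enolase
TK1215	TK1214	TRUE	TRUE	3	FALSE	membrane-bound sulfane reductase, adjacent subunit
TK2077	TK0574	TRUE	TRUE	5	FALSE	metallophosphoesterase, calcineurin superfamily
TK2077	TK0789	TRUE	TRUE	5	FALSE	glycerol-1-phosphate dehydrogenase [NAD(P)+]
TK2077	TK0930	TRUE	TRUE	5	FALSE	uncharacterized protein
TK2077	TK0953	TRUE	TRUE	5	FALSE	predicted ATPase, AAA superfamily, PIN and KH domains
TK2077	TK1328	TRUE	TRUE	5	FALSE	tRNA (1-methyladenosine) methyltransferase
TK2077	TK2012	TRUE	TRUE	5	FALSE	ferredoxin 3
TK2077	TK2093	TRUE	TRUE	5	FALSE	membrane-bound hydrogenase, [4Fe-4S] cluster-binding subunit, MBH-N
TK2077	TK2106	TRUE	TRUE	5	FALSE	enolase
TK2077	TK2074	TRUE	TRUE	4	FALSE	glutamate synthase, FDH-associated
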