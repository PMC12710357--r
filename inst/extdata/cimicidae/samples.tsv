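host_id	species	subfamily
C1	Afrocimex constrictus	Afrocimicinae
C5	Primicimex cavernis	Primicimicinae
C12	Cyanolicimex patagonicus	Haematosiphoninae
C19	Cacodmus villosus	Cacodminae
C21	Psitticimex uritui	Haematosiphoninae
C28	Cacodmus vicinus	Cacodminae
C41	Leptocimex duplicatus	Cacodminae
C44	Paracimex sp	Cimicinae
C49	Cimex vicarius	Cimicinae
C51	Cimex hirundinis	Cimicinae
C56	Cimex lectularius (bat)	Cimicinae
C57	Cimex lectularius (human)	Cimicinae
C61	Cimex hemipterus	Cimicinae
C66	Cimex adjunctus	Cimicinae
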