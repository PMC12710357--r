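strain_id	host_id	genus
Wolbachia_C1	C1	Wolbachia
Wolbachia_C5	C5	Wolbachia
Wolbachia_C12_high	C12	Wolbachia
Wolbachia_C12_low	C12	Wolbachia
Wolbachia_C21_high	C21	Wolbachia
Wolbachia_C21_low	C21	Wolbachia
Wolbachia_C44	C44	Wolbachia
Wolbachia_C49	C49	Wolbachia
Wolbachia_C51_high	C51	Wolbachia
Wolbachia_C51_low	C51	Wolbachia
Wolbachia_C56	C56	Wolbachia
Wolbachia_C57	C57	Wolbachia
Wolbachia_C61	C61	Wolbachia
Wolbachia_C66	C66	Wolbachia
Symbiopectobacterium_C19	C19	Symbiopectobacterium
Symbiopectobacterium_C28	C28	Symbiopectobacterium
Symbiopectobacterium_C41	C41	Symbiopectobacterium
Symbiopectobacterium_C57	C57	Symbiopectobacterium
Symbiopectobacterium_C61	C61	Symbiopectobacterium
Sodalis_C5	C5	Sodalis
Sodalis_C12	C12	Sodalis
Sodalis_C21	C21	Sodalis
Serratia_C44	C44	Serratia
Tisiphia_C1	C1	Tisiphia
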