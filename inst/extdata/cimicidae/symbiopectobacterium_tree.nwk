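((Symbiopectobacterium_C19,Symbiopectobacterium_C28),Symbiopectobacterium_C41,Symbiopectobacterium_C57,Symbiopectobacterium_C61);
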