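(Wolbachia_C1,(Wolbachia_C5,(Wolbachia_C12_high,(Wolbachia_C21_high,(Wolbachia_C12_low,(Wolbachia_C21_low,(Wolbachia_C51_low,(Wolbachia_C66,(Wolbachia_C49,(Wolbachia_C51_high,(Wolbachia_C44,(Wolbachia_C61,(Wolbachia_C56,Wolbachia_C57)))))))))))));
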