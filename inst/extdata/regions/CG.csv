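atom,region
C22,i
C21,i
C15,ii
C4,iii
C3,iii
C2,iii
C5,iii
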