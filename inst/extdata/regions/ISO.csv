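atom,region
C5,iii
C6,iii
C2,iii
C16,i
C18,i
C9,ii
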