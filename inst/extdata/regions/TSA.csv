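atom,region
O1,i
C13,i
N1,i
C11,i
C9,i
C16,ii
C6,ii
C2,ii
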