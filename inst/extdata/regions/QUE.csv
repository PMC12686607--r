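atom,region
C16,ii
C17,ii
C19,ii
C15,ii
C18,ii
O12,i
C2,i
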