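species,percent
C16:0,24.13
C16:1,14.70
C18:1,25.67
C16:2,0.44
C18:2,23.17
C16:3,9.89
C18:3,1.23
C20:5,0.77
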