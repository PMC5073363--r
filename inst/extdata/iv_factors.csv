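species,value,source
C12:0,0,saturated; no halogen addition
C14:0,0,saturated; no halogen addition
C14:1,1.0558,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C16:0,0,saturated; no halogen addition
C16:1,0.9455,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C16:2,1.9053,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C16:3,2.8797,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C16:4,3.8692,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C18:0,0,saturated; no halogen addition
C18:1,0.8561,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C18:2,1.7238,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C18:3,2.6035,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C18:4,3.4955,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C20:0,0,saturated; no halogen addition
C20:1,0.7869,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C20:4,3.1876,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C20:5,4.0098,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C22:0,0,saturated; no halogen addition
C22:1,0.7239,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C22:6,4.4460,calculated per EN 14214 Annex B convention: 253.81*db/MW(methyl ester)
C24:0,0,saturated; no halogen addition
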