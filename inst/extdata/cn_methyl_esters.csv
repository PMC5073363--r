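species,value,source
C12:0,61.4,methyl laurate; per-ester CN compilation (Knothe 2005 Fuel Process Technol 86:1059)
C14:0,66.2,methyl myristate; per-ester CN compilation (Knothe 2005)
C16:0,74.5,methyl palmitate; per-ester CN compilation (Knothe 2005)
C16:1,51.0,methyl palmitoleate; per-ester CN compilation (Knothe 2014 Prog Energy Combust Sci)
C18:0,86.9,methyl stearate; per-ester CN compilation (Knothe 2005)
C18:1,59.3,methyl oleate; per-ester CN compilation (Knothe 2005)
C18:2,38.2,methyl linoleate; per-ester CN compilation (Knothe 2005)
C18:3,22.7,methyl linolenate; per-ester CN compilation (Knothe 2005)
C20:0,100.0,methyl arachidate; literature estimate (long-chain saturated trend)
C20:5,24.4,methyl eicosapentaenoate; literature estimate for long-chain PUFA esters
C22:1,74.2,methyl erucate; per-ester CN compilation (Knothe 2005)
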