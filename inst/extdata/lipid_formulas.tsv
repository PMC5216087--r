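name	formula	rule
PC(31:0)	C39H78NO8P	[M+H]1+
PC(33:0)	C41H82NO8P	[M+H]1+
PC(33:0) 13C	C41H82NO8P	[M+H]1+ 13C
PC(35:0)	C43H86NO8P	[M+H]1+
Long-chain hydrocarbon C18:1	C18H34	[M+NH4]1+
Long-chain hydrocarbon C18:0	C18H36	[M+NH4]1+
Long-chain hydrocarbon C17:1	C17H34	[M+NH4]1+
Heptadecanoic acid	C17H34O2	[M+NH4]1+
Heptadecanoic acid 13C	C17H34O2	[M+NH4]1+ 13C
C17 sphinganine	C17H37NO2	[M+H]1+
C17 sphinganine 13C	C17H37NO2	[M+H]1+ 13C
Long-chain hydrocarbon C14:1	C14H28	[M+NH4]1+
Pentadecanal	C15H30O	[M+NH4]1+
Hydroxy-dihydro-ethanovitamin D3	C29H48O2	[M+H]1+
Hydroxy-dihydro-ethanovitamin D3 13C	C29H48O2	[M+H]1+ 13C
PC(O-32:6)	C44H78NO7P	[M+H]1+
PC(O-38:6) 13C	C46H82NO7P	[M+H]1+ 13C
N-(trans-tetradecanoyl)-deoxysphing-4-enine-1-sulphonate	C32H61NO5S	[M+NH4]1+
N-(trans-tetradecanoyl)-deoxysphing-4-enine-1-sulphonate 13C	C32H61NO5S	[M+NH4]1+ 13C
SM(d18:0/16:0)	C39H82N2O6P	[M+H]1+
SM(d18:0/16:0) 13C	C39H82N2O6P	[M+H]1+ 13C
PC(O-34:3)	C42H80NO7P	[M+H]1+
PC(O-34:2)	C42H82NO7P	[M+H]1+
PC(O-34:2) 13C	C42H82NO7P	[M+H]1+ 13C
Unknown phospholipid 776.6	C42H83NO9P	[M+H]1+
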