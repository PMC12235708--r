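name	targets	delta_formula	delta_mass	arp_labelable	pathway
glycoaldehyde_aldimine	K,C	C2H2O		TRUE	RCS
glyoxal_aldimine	K	C2H2O2		TRUE	RCS
acrolein_michael	K,C,H	C3H4O		TRUE	RCS
mda_mg_michael	K	C3H4O2		TRUE	RCS
mda_mg_schiff	K,C	C3H2O		TRUE	RCS
hexose_glycation	K	C6H10O5		TRUE	RCS
aminoadipic_semialdehyde	K	O1N-1H-3		TRUE	MCO
threonine_oxo	T	H-2		TRUE	MCO
histidine_oxo	H	O		TRUE	MCO
methionine_aldehyde	M	O1C-1H-4S-1		TRUE	MCO
unknown_68	K		68.026	TRUE	UNKNOWN
unknown_70	K		70.017	TRUE	UNKNOWN
unknown_82	K	C3H2N2O		TRUE	UNKNOWN
unknown_86	K,C		86.012	TRUE	UNKNOWN
unknown_96	K		96.021	TRUE	UNKNOWN
unknown_106	K		106.006	TRUE	UNKNOWN
carbamidomethyl	C	C2H3NO		FALSE	NONE
methionine_oxidation	M	O		FALSE	NONE
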