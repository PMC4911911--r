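# Bundled motif definitions (IUPAC RNA; T is read as U).
# fbe: canonical PUF binding element. sevenmer: FBE-like 7-mer enriched in
# peaks lacking an FBE; sevenmer_refined: its optimal form. halfmer_*: UGU-
# based half-mers. invitro_1..4: U/G-rich alternate elements of the kind
# recovered by in vitro selection -- the exact published strings are figure-
# only, so these are SYNTHETIC PLACEHOLDER patterns; edit this table to use
# your own. egl4: neuronal-target element, included for scanning only.
name	pattern	context
fbe	UGUNNNAU	NA
fbe_m1c	UGUNNNAU	C@-1
fbe_m2c	UGUNNNAU	C@-2
sevenmer	UGURNAU	NA
sevenmer_refined	UGUGAAUR	NA
halfmer_ugu	UGU	NA
halfmer_cugu	CUGU	NA
invitro_1	UGUGUUGU	NA
invitro_2	UUGUGUGU	NA
invitro_3	GUUGUUUG	NA
invitro_4	UGUUUGUU	NA
egl4	UGUGUAUAUA	NA
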