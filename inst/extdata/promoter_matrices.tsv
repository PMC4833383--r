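pri_mirna	n_printed	site	distance_tss
mir-181a2/181b2	2	ataattggttt	-401
mir-181a2/181b2	2	agcccaatcag	-131
mir-21	3	tatccaatccc	218
mir-21	3	atcccaatcat	-416
mir-21	3	ttaattggttc	-102
mir-301b/130b	3	cggccaatgag	-55
mir-301b/130b	3	gagattggagc	-254
mir-301b/130b	3	gggccaatcgg	-140
mir-17/18a/20a/19b1/92a1	1	gtgattggcgg	-104
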