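pup_id	sex	H2Afb3	Gm14920	H2Afb2
L74-1	female	XX (wt)	XX (wt)	XX (wt)
L74-2	female	XX (wt)	XX (wt)	XX (wt)
L74-3	female	XX (wt)	XX (wt)	XX (wt)
L74-4	male	XY (wt)	XY (wt)	XY (wt)
L74-5	male	X^∆5+286^ Y	X^∆15^ Y	X^∆17^ Y
L79-1	female	X^∆10^ X^∆10^	X^∆12^ X^∆12^ Chimera of b/∆/c	X^∆15^ X^∆15^ Chimera of c/∆/b
L89-1	female	X^∆22^ X^∆160^	X^∆5^ X^∆17^ Chimera c/∆/b)	X^∆5^ X^∆5^
L89-2	male	X^∆65^ Y	X^C/T, A/G^ Y	X^∆42^ Y Chimera b/∆/c)
L89-3	male	X^∆26^ Y Chimera c/∆/a)	X^∆10^ Y Chimera b/∆/c)	X^∆10^ Y Chimera b/∆/c)
L90-1	female	XX (wt)	XX (wt)	XX (wt)
L90-2	female	XX (wt)	XX (wt)	XX (wt)
L90-3	female	X^∆28^ X^∆5^	X^∆10^ X^∆10^	X^∆64^ X^∆64^
L90-4	female	X^∆15^ X^∆10^	No successful PCR amplification	No successful PCR amplification.
L90-5	female	XX (wt)	XX (wt)	XX (wt)
L90-6	female	X^∆17^ X^∆17^ Chimera c/∆/a)	X^∆5^ X^∆5^ Chimera b/∆/c)	X^∆5^ X^∆5^ Chimera c/b/∆/c)
L90-7	female	XX (wt)	XX (wt)	XX (wt)
L90-8	male	X^∆16^ Y	X^∆17^ Y Chimera c/∆/c/b)	No successful PCR amplification.
L90-9	male	XY (wt)	XY (wt)	XY (wt)
L90-10	male	XY (wt)	XY (wt)	XY (wt)
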