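# 1H and 13C chemical shifts of S-adenosylmethionine at 25 C.
# Reference fixture only: nothing in the package computes these values.
Atom	Multiplet	Shift_1H_ppm	Shift_13C_ppm
H2	s	8.27	155.70
H8	s	8.30	143.73
H1'	d	6.11	91.81
H2'	t	4.96	75.16
H3'	t	4.60	75.36
H4'	mult.	4.57	80.92
H5'	d	3.93	46.87
H5''	d	4.04	46.87
MET-CH3	s	2.98	26.13
Halpha	t	3.78	55.35
Hbeta	quart.	2.34	27.69
Hgamma	t	3.47	41.22
Hgamma'	t	3.68	41.22
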