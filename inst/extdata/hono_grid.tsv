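# Published 6D HONO primitive DVR grid definition: DVR family (HO = Hermite
# harmonic oscillator, cos = cosine), point count, coordinate range.
# Lengths in bohr; u1/u2 are cosines of the bending angles; phi is the
# torsion in radians over [0, pi].
dof	dvr	n	first	last
d_OH	HO	18	1.30	2.45
d_NO	HO	13	1.90	2.60
u_2	HO	13	-0.65	-0.10
d_ON	HO	16	2.10	3.25
u_1	HO	18	-0.65	0.25
phi	cos	32	0	3.14159265358979
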