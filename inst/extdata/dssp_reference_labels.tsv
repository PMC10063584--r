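# Reference secondary-structure labels for the deterministic backbone
# fixtures built by build_peptide() (helix: phi=-57 psi=-47 n=15;
# ext: 180/180 n=15; g310: -49/-26 n=15; coil: n=20, phi/psi from
# runif with set.seed(42)). Labels computed once with a reference
# DSSP implementation (mdtraj.compute_dssp, full code set; blank
# loop code stored as C).
fixture	resid	dssp
helix	1	C
helix	2	H
helix	3	H
helix	4	H
helix	5	H
helix	6	H
helix	7	H
helix	8	H
helix	9	H
helix	10	H
helix	11	H
helix	12	H
helix	13	H
helix	14	H
helix	15	C
ext	1	C
ext	2	C
ext	3	C
ext	4	C
ext	5	C
ext	6	C
ext	7	C
ext	8	C
ext	9	C
ext	10	C
ext	11	C
ext	12	C
ext	13	C
ext	14	C
ext	15	C
g310	1	C
g310	2	G
g310	3	G
g310	4	G
g310	5	G
g310	6	G
g310	7	G
g310	8	G
g310	9	G
g310	10	G
g310	11	G
g310	12	G
g310	13	G
g310	14	G
g310	15	C
coil	1	C
coil	2	C
coil	3	S
coil	4	C
coil	5	S
coil	6	S
coil	7	S
coil	8	S
coil	9	S
coil	10	C
coil	11	S
coil	12	S
coil	13	C
coil	14	S
coil	15	C
coil	16	C
coil	17	C
coil	18	C
coil	19	C
coil	20	C
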