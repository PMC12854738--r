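# Ideal ribonucleotide templates

Heavy-atom ideal coordinates for the four ribonucleotides (A, C, G, U),
taken from the PDB Chemical Component Dictionary idealised geometries and
stored as tab-separated text (`atom`, `element`, `x`, `y`, `z`; Angstrom).
Used by `build_helix_fixture()` to construct idealised A-form helix
fixtures with known base pairing. The sugar of these templates sits at a
pseudorotation phase of ~270 deg; descriptor tests treat pucker via an
independent oracle rather than assuming a canonical conformer.
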