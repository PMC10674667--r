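# TIP4P-EW rigid four-site water model (Horn et al. 2004).
# O carries the Lennard-Jones site, the massless M site on the H-O-H bisector
# (O-M distance 0.125 A) carries the negative charge. Geometry (O-H 0.9572 A,
# H-O-H 104.52 deg) is held rigid by SHAKE constraints; the template carries
# no bonded interaction terms. Hydrogens and M have no LJ interaction
# (epsilon = 0; the nominal sigma only satisfies the sigma > 0 contract).

[types]
# species type class element q sigma epsilon
TIP4PEW OW OW O  0.00000 3.16435 0.680946
TIP4PEW HW HW H  0.52422 1.00000 0.0
TIP4PEW MW MW M -1.04844 1.00000 0.0

[bonds]

[angles]

[torsions]
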