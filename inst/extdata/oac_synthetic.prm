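# SYNTHETIC stand-in parameter set for the acetate anion [OAc]-.
#
# The full published acetate set belongs to the earlier force-field releases
# and is not embedded here. This file is a synthetic reconstruction for
# testing and reduced-scale demonstration runs: the carboxylate oxygen charge
# (-0.66 e) is the documented value; the remaining charges close the scaled
# net ionic charge at -0.82 e and the Lennard-Jones / bonded values are
# OPLS-AA-style choices. Not a substitute for the published acetate set.
#
# CO-O2 bond, O2-CO-O2 angle and HC-CT bond parameters are inherited from the
# embedded benzoate/cation tables (identical classes) and are not repeated.

[types]
# species type class element q sigma epsilon
OAc CO CO C  0.760 3.90 0.4393
OAc O2 O2 O -0.660 2.96 0.8786
OAc CT CT C -0.350 3.50 0.2760
OAc HC HC H  0.030 2.50 0.1260

[bonds]
CT CO 1.522 1900.0

[angles]
CT CO O2 117.0 550.2
HC CT CO 109.5 292.9

[torsions]
HC CT CO O2 0.0 0.0 0.0 0.0
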