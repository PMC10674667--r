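# SYNTHETIC stand-in parameter set for the 1-ethyl-3-methylimidazolium
# cation [EMIm]+.
#
# The full published imidazolium set belongs to the earlier force-field
# releases and is not embedded here. This file is a synthetic reconstruction
# for testing and plumbing: the aromatic ring-proton values (q = +0.150 e,
# sigma = 1.62 A) are the documented ones; the remaining charges close the
# scaled net ionic charge at +0.82 e and the other values are OPLS-AA-style
# choices. Not a substitute for the published imidazolium set.

[types]
# species type class element q sigma epsilon
EMIm NA  NA N  0.120 3.25 0.7110
EMIm CR  CR C  0.120 3.55 0.2930
EMIm CW  CW C -0.190 3.55 0.2930
EMIm HCR HA H  0.150 1.62 0.1260
EMIm HCW HA H  0.150 1.62 0.1260
EMIm C1  CT C -0.240 3.50 0.2760
EMIm H1  HC H  0.148 2.42 0.1260
EMIm CE  CT C -0.080 3.50 0.2760
EMIm HC  HC H  0.070 2.50 0.1260

[bonds]
CR NA 1.330 3500.0
CR HA 1.080 2700.0

[angles]
NA CR NA 109.9 585.0
NA CR HA 125.1 200.0
CR NA CW 108.0 500.0
CR NA CT 126.0 250.0

[torsions]
CW NA CR NA 0.0 19.46 0.0 0.0
CW NA CR HA 0.0 19.46 0.0 0.0
CT NA CR NA 0.0 19.46 0.0 0.0
CT NA CR HA 0.0 19.46 0.0 0.0
CR NA CW CW 0.0 12.55 0.0 0.0
CR NA CW HA 0.0 12.55 0.0 0.0
CR NA CT HC 0.0 0.0 0.0 0.0
CR NA CT CT 0.1 1.0 0.1 -0.3
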