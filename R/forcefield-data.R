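# Embedded BILFF parameter set for [EMTr]+ and [OBz]-.
#
# Atom types carry the non-bonded parameters (partial charge q in e,
# Lennard-Jones sigma in Angstrom and epsilon in kJ/mol); atom classes key the
# bonded parameters. Type names are scoped per species (the ipso carbon of
# benzoate and the N-CH2 carbon of the cation are both called C1 but carry
# different parameters). CM/HM/HE are aliases used in structure drawings for
# the N-methyl carbon and the methyl/ethyl hydrogens; they resolve to C1, H1
# and HC respectively, which closes the cation charge sum at +0.820 e exactly.

.bilff_types <- function() {
  x <- read.table(header = TRUE, stringsAsFactors = FALSE, na.strings = character(0), text = "
species type class element q      sigma epsilon
EMTr    C1   CT    C       -0.187 3.34  0.2760
EMTr    CE   CT    C       -0.054 3.34  0.2760
EMTr    CW   CW    C       -0.144 3.38  0.2930
EMTr    HCW  HA    H        0.191 1.48  0.1260
EMTr    HC   HC    H        0.070 2.38  0.1260
EMTr    H1   HC    H        0.148 2.38  0.1260
EMTr    NR   NR    N       -0.204 3.10  0.7110
EMTr    NA   NA    N        0.204 3.10  0.7110
OBz     C1   CA    C        0.005 3.70  0.2929
OBz     C2   CA    C       -0.118 3.70  0.2929
OBz     C3   CA    C       -0.121 3.70  0.2929
OBz     C4   CA    C       -0.299 3.70  0.2929
OBz     CO   CO    C        0.398 3.90  0.4393
OBz     H2   HA    H        0.070 2.42  0.1255
OBz     H3   HA    H        0.157 2.42  0.1255
OBz     H4   HA    H        0.200 2.42  0.1255
OBz     O2   O2    O       -0.550 2.80  0.8786
")
  x$mass <- atomic_weight(x$element)
  x
}

.bilff_bonds <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, na.strings = character(0), text = "
class1 class2 l0    kl
NA     NR     1.344 3199.2
CW     HA     1.088 2633.8
CW     NA     1.375 3108.7
CW     CW     1.386 3773.2
NA     CT     1.488 2046.3
HC     CT     1.099 2679.4
CT     CT     1.533 2125.5
CA     CA     1.387 3274.1
CA     HA     1.088 2707.4
CA     CO     1.504 1906.9
CO     O2     1.282 4273.1
")
}

.bilff_angles <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, na.strings = character(0), text = "
class1 class2 class3 theta0 ktheta
CW     NA     NR     112.1  568.7
NR     NA     CT     118.6  396.5
NA     NR     NA     104.4  610.1
NA     CT     CT     110.9  361.2
NA     CW     CW     107.0  579.7
NA     CW     HA     120.8  200.9
CW     CW     HA     131.7  190.5
NA     CT     HC     107.2  375.9
CT     CT     HC     111.4  296.2
HC     CT     HC     109.2  226.5
CW     NA     CT     125.2  242.9
CA     CA     CA     120.0  446.0
CA     CA     HA     120.0  258.1
CA     CA     CO     120.0  397.6
CA     CO     O2     117.0  550.2
O2     CO     O2     126.0  735.9
")
}

.bilff_torsions <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, na.strings = character(0), text = "
class1 class2 class3 class4 V1     V2      V3     V4
CW     NA     NR     NA     0.0000 19.4600 0.0000 0.0000
CT     NA     NR     NA     0.0000 19.4600 0.0000 0.0000
NR     NA     CW     CW     0.0000 12.5500 0.0000 0.0000
NR     NA     CW     HA     0.0000 12.5500 0.0000 0.0000
NR     NA     CT     HC     0.0000 0.0000  0.0000 0.0000
NR     NA     CT     CT     0.1000 1.0000  0.1000 -0.3000
CT     NA     CW     CW     0.0000 12.5500 0.0000 0.0000
CT     NA     CW     HA     0.0000 12.5500 0.0000 0.0000
NA     CW     CW     NA     0.0000 65.0000 0.0000 0.0000
NA     CW     CW     HA     0.0000 44.9800 0.0000 0.0000
HA     CW     CW     HA     0.0000 30.0000 0.0000 0.0000
CW     NA     CT     HC     0.1000 0.2000  0.0000 0.0000
CW     NA     CT     CT     0.4000 1.0000  0.0000 0.2000
NA     CT     CT     HC     0.0000 0.0000  0.3670 0.0000
HC     CT     CT     HC     0.0000 0.0000  1.2552 0.0000
CA     CA     CA     CA     0.0000 30.334  0.0000 0.0000
HA     CA     CA     CA     0.0000 30.334  0.0000 0.0000
HA     CA     CA     CO     0.0000 30.334  0.0000 0.0000
HA     CA     CA     HA     0.0000 30.334  0.0000 0.0000
CA     CA     CA     CO     0.0000 30.334  0.0000 0.0000
CA     CA     CO     O2     0.0000 8.000   0.0000 0.0000
")
}
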