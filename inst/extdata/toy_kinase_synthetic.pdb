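REMARK   1 SYNTHETIC TOY KINASE COORDINATES (NOT A DEPOSITED STRUCTURE)
REMARK   1 GEOMETRY CONSTRUCTED FOR ACTIVATION-SEGMENT CONTACT TESTS
ATOM      1  CA  ASP A 576       0.800   9.200   0.000  1.00  0.00           C
ATOM      2  CB  ASP A 576       0.400   8.600   0.000  1.00  0.00           C
ATOM      3  OD1 ASP A 576       0.000   8.000   0.000  1.00  0.00           O
ATOM      4  CA  ASP A 594      -3.600   7.200   0.000  1.00  0.00           C
ATOM      5  OD1 ASP A 594      -3.000   6.500   0.000  1.00  0.00           O
ATOM      6  CA  GLY A 596      12.000  12.000   0.000  1.00  0.00           C
ATOM      7  N   THR A 599      -0.600   3.200   0.000  1.00  0.00           N
ATOM      8  CA  THR A 599       0.000   3.800   0.000  1.00  0.00           C
ATOM      9  OG1 THR A 599       0.500   4.800   0.000  1.00  0.00           O
ATOM     10  N   VAL A 600      -1.000  -0.800   0.000  1.00  0.00           N
ATOM     11  CA  VAL A 600       0.000   0.000   0.000  1.00  0.00           C
ATOM     12  CB  VAL A 600       1.500   0.000   0.000  1.00  0.00           C
ATOM     13  CA  LYS A 601       3.800   2.000   0.000  1.00  0.00           C
ATOM     14  CZ  PHE A 468       5.500   0.000   0.000  1.00  0.00           C
ATOM     15  CE1 PHE A 468       6.300   0.900   0.000  1.00  0.00           C
ATOM     16  CA  LEU A 505       0.000   0.000   5.000  1.00  0.00           C
ATOM     17  CD1 LEU A 505       0.800   0.400   5.600  1.00  0.00           C
END
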