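# In-code PDB fixtures (built at test time; nothing binary on disk).

# five CA residues of chain A with known coordinates, plus one HETATM and
# one chain-B residue that must be ignored when chain A is requested
fixture_pdb_basic <- function() {
  paste(c(
    "HEADER    SYNTHETIC FIXTURE",
    "ATOM      1  N   ALA A   1      10.000  10.000  10.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.000  10.000  10.000  1.00 10.00           C",
    "ATOM      3  CA  GLY A   2      14.500  10.250  10.000  1.00 10.00           C",
    "ATOM      4  CA  SER A   3      17.750  11.000  11.500  1.00 10.00           C",
    "ATOM      5  CA  LEU A   4      21.000  12.125  13.000  1.00 10.00           C",
    "ATOM      6  CA  LYS A   5      24.250  13.000  15.750  1.00 10.00           C",
    "ATOM      7  CA  VAL B   1       1.000   2.000   3.000  1.00 10.00           C",
    "HETATM    8  CA  CA  A 101       5.000   5.000   5.000  1.00 10.00          CA",
    "END"), collapse = "\n")
}

fixture_pdb_basic_coords <- function() {
  matrix(c(11.000, 10.000, 10.000,
           14.500, 10.250, 10.000,
           17.750, 11.000, 11.500,
           21.000, 12.125, 13.000,
           24.250, 13.000, 15.750), ncol = 3, byrow = TRUE)
}

# residue 2 has altlocs A (occupancy 0.40) and B (0.60): B must win;
# residue 3 has altlocs A and B at equal occupancy: A must win
fixture_pdb_altloc <- function() {
  paste(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA AGLY A   2       3.800   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CA BGLY A   2       3.900   0.100   0.000  0.60 10.00           C",
    "ATOM      4  CA ASER A   3       7.600   0.000   0.000  0.50 10.00           C",
    "ATOM      5  CA BSER A   3       7.700   0.200   0.000  0.50 10.00           C",
    "ATOM      6  CA  LEU A   4      11.400   0.000   0.000  1.00 10.00           C",
    "END"), collapse = "\n")
}
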