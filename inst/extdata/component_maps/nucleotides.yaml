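# Residue/atom-name -> component map for PDB input.
#
# Covers the four 2'-deoxyribonucleoside 5'-monophosphate residues
# (DA/DG/DC/DT), base-only residues (ADE/GUA/CYT/THY), and the internal
# BAS/RIB/PHO residues written by this package ("*" matches any atom name).
#
# Partition choice for the sugar-phosphate backbone: the bridging O5'
# oxygen is counted with the PHOSPHATE group (it caps the phosphoester
# bond), while O3' (a sugar hydroxyl in a 5'-monophosphate) is counted
# with the RIBOSE.  Terminal phosphate oxygens OP1/OP2/OP3 (older
# O1P/O2P/O3P spellings accepted) are PHOSPHATE.
water_residues: [HOH, WAT, TIP3]
residues:
  BAS: {"*": BASE}
  RIB: {"*": RIBOSE}
  PHO: {"*": PHOSPHATE}
  ADE:
    N9: BASE
    C8: BASE
    N7: BASE
    C5: BASE
    C4: BASE
    N3: BASE
    C2: BASE
    N1: BASE
    C6: BASE
    N6: BASE
    H2: BASE
    H8: BASE
    H61: BASE
    H62: BASE
  GUA:
    N9: BASE
    C8: BASE
    N7: BASE
    C5: BASE
    C4: BASE
    N3: BASE
    C2: BASE
    N1: BASE
    C6: BASE
    O6: BASE
    N2: BASE
    H1: BASE
    H8: BASE
    H21: BASE
    H22: BASE
  CYT:
    N1: BASE
    C2: BASE
    O2: BASE
    N3: BASE
    C4: BASE
    N4: BASE
    C5: BASE
    C6: BASE
    H5: BASE
    H6: BASE
    H41: BASE
    H42: BASE
  THY:
    N1: BASE
    C2: BASE
    O2: BASE
    N3: BASE
    C4: BASE
    O4: BASE
    C5: BASE
    C7: BASE
    C5M: BASE
    C6: BASE
    H3: BASE
    H6: BASE
    H71: BASE
    H72: BASE
    H73: BASE
  DA:
    N9: BASE
    C8: BASE
    N7: BASE
    C5: BASE
    C4: BASE
    N3: BASE
    C2: BASE
    N1: BASE
    C6: BASE
    N6: BASE
    H2: BASE
    H8: BASE
    H61: BASE
    H62: BASE
    P: PHOSPHATE
    OP1: PHOSPHATE
    OP2: PHOSPHATE
    OP3: PHOSPHATE
    O1P: PHOSPHATE
    O2P: PHOSPHATE
    O3P: PHOSPHATE
    "O5'": PHOSPHATE
    HOP2: PHOSPHATE
    HOP3: PHOSPHATE
    "C5'": RIBOSE
    "C4'": RIBOSE
    "O4'": RIBOSE
    "C3'": RIBOSE
    "O3'": RIBOSE
    "C2'": RIBOSE
    "C1'": RIBOSE
    "H5'": RIBOSE
    "H5''": RIBOSE
    "H4'": RIBOSE
    "H3'": RIBOSE
    "HO3'": RIBOSE
    "H2'": RIBOSE
    "H2''": RIBOSE
    "H1'": RIBOSE
  DG:
    N9: BASE
    C8: BASE
    N7: BASE
    C5: BASE
    C4: BASE
    N3: BASE
    C2: BASE
    N1: BASE
    C6: BASE
    O6: BASE
    N2: BASE
    H1: BASE
    H8: BASE
    H21: BASE
    H22: BASE
    P: PHOSPHATE
    OP1: PHOSPHATE
    OP2: PHOSPHATE
    OP3: PHOSPHATE
    O1P: PHOSPHATE
    O2P: PHOSPHATE
    O3P: PHOSPHATE
    "O5'": PHOSPHATE
    HOP2: PHOSPHATE
    HOP3: PHOSPHATE
    "C5'": RIBOSE
    "C4'": RIBOSE
    "O4'": RIBOSE
    "C3'": RIBOSE
    "O3'": RIBOSE
    "C2'": RIBOSE
    "C1'": RIBOSE
    "H5'": RIBOSE
    "H5''": RIBOSE
    "H4'": RIBOSE
    "H3'": RIBOSE
    "HO3'": RIBOSE
    "H2'": RIBOSE
    "H2''": RIBOSE
    "H1'": RIBOSE
  DC:
    N1: BASE
    C2: BASE
    O2: BASE
    N3: BASE
    C4: BASE
    N4: BASE
    C5: BASE
    C6: BASE
    H5: BASE
    H6: BASE
    H41: BASE
    H42: BASE
    P: PHOSPHATE
    OP1: PHOSPHATE
    OP2: PHOSPHATE
    OP3: PHOSPHATE
    O1P: PHOSPHATE
    O2P: PHOSPHATE
    O3P: PHOSPHATE
    "O5'": PHOSPHATE
    HOP2: PHOSPHATE
    HOP3: PHOSPHATE
    "C5'": RIBOSE
    "C4'": RIBOSE
    "O4'": RIBOSE
    "C3'": RIBOSE
    "O3'": RIBOSE
    "C2'": RIBOSE
    "C1'": RIBOSE
    "H5'": RIBOSE
    "H5''": RIBOSE
    "H4'": RIBOSE
    "H3'": RIBOSE
    "HO3'": RIBOSE
    "H2'": RIBOSE
    "H2''": RIBOSE
    "H1'": RIBOSE
  DT:
    N1: BASE
    C2: BASE
    O2: BASE
    N3: BASE
    C4: BASE
    O4: BASE
    C5: BASE
    C7: BASE
    C5M: BASE
    C6: BASE
    H3: BASE
    H6: BASE
    H71: BASE
    H72: BASE
    H73: BASE
    P: PHOSPHATE
    OP1: PHOSPHATE
    OP2: PHOSPHATE
    OP3: PHOSPHATE
    O1P: PHOSPHATE
    O2P: PHOSPHATE
    O3P: PHOSPHATE
    "O5'": PHOSPHATE
    HOP2: PHOSPHATE
    HOP3: PHOSPHATE
    "C5'": RIBOSE
    "C4'": RIBOSE
    "O4'": RIBOSE
    "C3'": RIBOSE
    "O3'": RIBOSE
    "C2'": RIBOSE
    "C1'": RIBOSE
    "H5'": RIBOSE
    "H5''": RIBOSE
    "H4'": RIBOSE
    "H3'": RIBOSE
    "HO3'": RIBOSE
    "H2'": RIBOSE
    "H2''": RIBOSE
    "H1'": RIBOSE
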