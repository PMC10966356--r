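# Covalent topology of the 20 standard amino acids (heavy atoms).
# Backbone bonds N-CA, CA-C, C-O, C-OXT and CA-CB are implied for every
# residue (CB only where present); the peptide bond C(i)-N(i+1) is added
# at parse time. Hydrogens are attached by name in code (HB2 -> CB etc.).
residues:
  ALA: {bonds: []}
  ARG: {bonds: [[CB, CG], [CG, CD], [CD, NE], [NE, CZ], [CZ, NH1], [CZ, NH2]]}
  ASN: {bonds: [[CB, CG], [CG, OD1], [CG, ND2]]}
  ASP: {bonds: [[CB, CG], [CG, OD1], [CG, OD2]]}
  CYS: {bonds: [[CB, SG]]}
  GLN: {bonds: [[CB, CG], [CG, CD], [CD, OE1], [CD, NE2]]}
  GLU: {bonds: [[CB, CG], [CG, CD], [CD, OE1], [CD, OE2]]}
  GLY: {bonds: []}
  HIS: {bonds: [[CB, CG], [CG, ND1], [CG, CD2], [ND1, CE1], [CD2, NE2], [CE1, NE2]]}
  ILE: {bonds: [[CB, CG1], [CB, CG2], [CG1, CD1]]}
  LEU: {bonds: [[CB, CG], [CG, CD1], [CG, CD2]]}
  LYS: {bonds: [[CB, CG], [CG, CD], [CD, CE], [CE, NZ]]}
  MET: {bonds: [[CB, CG], [CG, SD], [SD, CE]]}
  PHE: {bonds: [[CB, CG], [CG, CD1], [CG, CD2], [CD1, CE1], [CD2, CE2], [CE1, CZ], [CE2, CZ]]}
  PRO: {bonds: [[CB, CG], [CG, CD], [CD, "N"]]}
  SER: {bonds: [[CB, OG]]}
  THR: {bonds: [[CB, OG1], [CB, CG2]]}
  TRP: {bonds: [[CB, CG], [CG, CD1], [CG, CD2], [CD1, NE1], [NE1, CE2], [CD2, CE2], [CD2, CE3], [CE3, CZ3], [CZ3, CH2], [CH2, CZ2], [CZ2, CE2]]}
  TYR: {bonds: [[CB, CG], [CG, CD1], [CG, CD2], [CD1, CE1], [CD2, CE2], [CE1, CZ], [CE2, CZ], [CZ, OH]]}
  VAL: {bonds: [[CB, CG1], [CB, CG2]]}
# Residues without CB in the template
no_cb: [GLY]
# D-amino-acid residue names mapped to their L templates; these force is_D
d_aliases:
  DAL: ALA
  DAR: ARG
  DSG: ASN
  DAS: ASP
  DCY: CYS
  DGN: GLN
  DGL: GLU
  DHI: HIS
  DIL: ILE
  DLE: LEU
  DLY: LYS
  MED: MET
  DPN: PHE
  DPR: PRO
  DSN: SER
  DTH: THR
  DTR: TRP
  DTY: TYR
  DVA: VAL
# Modified residues kept from HETATM records, mapped to a standard template
het_aliases:
  MSE: MET
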