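# Demo eight-assay multiplexed panel.
# Protein sequences are synthetic assembled region fragments shipped with the
# package; epitope coordinates are local to those regions.
proteins: demo_proteins.fasta
tolerances:
  linear_da: 0.25
  linear_fallback_da: 0.5
  reflector_ppm: 25
labels:
  K: 8
  R: 10
assays:
  - id: EBP1_TOT
    accession: Q13541
    protein: FourEBP1_region
    site: "Total, C-terminal"
    epitope: {start: 96, end: 105}
    protease: trypsin
    max_missed: 2
  - id: EBP1_P37_46
    accession: Q13541
    protein: FourEBP1_region
    site: "p(T37 or T46)"
    epitope: {start: 22, end: 33}
    required_mods:
      - {position: 24, name: phospho}
      - {position: 33, name: phospho}
    required_semantics: any
    protease: trypsin
    max_missed: 1
  - id: EBP1_P65_70
    accession: Q13541
    protein: FourEBP1_region
    site: "p(S65 or T70)"
    epitope: {start: 51, end: 60}
    required_mods:
      - {position: 52, name: phospho}
      - {position: 57, name: phospho}
    required_semantics: any
    protease: trypsin
    max_missed: 2
  - id: AKT1_TOT
    accession: P31749
    protein: AKT1_region
    site: "Total, C-terminal"
    epitope: {start: 8, end: 20}
    protease: trypsin
    max_missed: 0
  - id: MTOR_S2448
    accession: P42345
    protein: MTOR_region
    site: "p(S2448)"
    epitope: {start: 5, end: 15}
    required_mods:
      - {position: 9, name: phospho}
    protease: trypsin
    max_missed: 1
  - id: CTNNB1_S675
    accession: P35222
    protein: CTNNB1_region
    site: "p(S675)"
    epitope: {start: 4, end: 14}
    required_mods:
      - {position: 6, name: phospho}
    protease: trypsin
    max_missed: 1
  - id: BAD_S75
    accession: Q92934
    protein: BAD_region
    site: "p(S75)"
    epitope: {start: 7, end: 27}
    required_mods:
      - {position: 9, name: phospho}
    protease: trypsin
    max_missed: 1
  - id: RPS6_S235_236
    accession: P62753
    protein: RPS6_region
    site: "p(S235 & S236)"
    epitope: {start: 6, end: 22}
    required_mods:
      - {position: 8, name: phospho}
      - {position: 9, name: phospho}
    variable_mod: phospho
    variable_residues: ST
    max_extra: 3
    protease: trypsin
    max_missed: 3
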