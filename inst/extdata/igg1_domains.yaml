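# Six-bead domain definition for a full-length human IgG1 (e.g. crystal
# structure 1HZH: heavy chains H and K, light chains L and M).
#
# NOTE: these residue ranges are a RECONSTRUCTION from standard IgG1 domain
# boundaries in EU numbering (VH ~1-117, CH1 ~118-215, hinge ~216-230,
# CH2 ~231-340, CH3 ~341-447; VL ~1-107, CL ~108-214). They are not taken
# from any published per-bead residue table and should be adjusted to the
# structure at hand.
mode: antibody
beads:
  - id: 1
    label: Fc_CH3
    select:
      - {chain: H, resid: [341, 447]}
      - {chain: K, resid: [341, 447]}
  - id: 2
    label: Fc_CH2
    select:
      - {chain: H, resid: [231, 340]}
      - {chain: K, resid: [231, 340]}
  - id: 3
    label: Fab1_CH1_CL
    select:
      - {chain: H, resid: [118, 215]}
      - {chain: L, resid: [108, 214]}
  - id: 4
    label: Fab1_VH_VL
    select:
      - {chain: H, resid: [1, 117]}
      - {chain: L, resid: [1, 107]}
  - id: 5
    label: Fab2_CH1_CL
    select:
      - {chain: K, resid: [118, 215]}
      - {chain: M, resid: [108, 214]}
  - id: 6
    label: Fab2_VH_VL
    select:
      - {chain: K, resid: [1, 117]}
      - {chain: M, resid: [1, 107]}
fragments:
  hinge:
    - {chain: H, resid: [216, 230]}
    - {chain: K, resid: [216, 230]}
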