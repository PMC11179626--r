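# Example collective-variable definitions over serum-albumin subdomain
# residue ranges (backbone heavy atoms of chain A, mature-protein numbering:
# domain I ~ 1-195, II ~ 196-383, III ~ 384-585; subdomain split at the
# midpoints). These ranges are PLACEHOLDERS illustrating the configuration
# format -- they are not an authoritative reproduction of any published CV
# set. Substitute your own selections for production analyses.
cvs:
  - label: D1
    kind: dihedral
    groups:
      - {chain: A, resno: [108, 195], backbone: true}   # subdomain IB
      - {chain: A, resno: [1, 107],  backbone: true}    # subdomain IA
      - {chain: A, resno: [196, 297], backbone: true}   # subdomain IIA
      - {chain: A, resno: [298, 383], backbone: true}   # subdomain IIB
  - label: P1
    kind: planar_angle
    groups:
      - {chain: A, resno: [1, 107],  backbone: true}
      - {chain: A, resno: [196, 297], backbone: true}
      - {chain: A, resno: [298, 383], backbone: true}
  - label: R1
    kind: distance
    groups:
      - {chain: A, resno: [1, 195],  backbone: true}    # domain I
      - {chain: A, resno: [196, 383], backbone: true}   # domain II
  - label: R2
    kind: distance
    groups:
      - {chain: A, resno: [1, 107],  backbone: true}
      - {chain: A, resno: [196, 297], backbone: true}
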