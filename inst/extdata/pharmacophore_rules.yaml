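# Versioned 2D pharmacophore perception rules.
# Each feature family can be toggled and parameterised here; the
# matchers themselves are graph-pattern rules implemented in the
# package (see ?perceiveFeatures for the rule semantics).
version: "1.0"
features:
  HBD:
    enabled: true            # N/O bearing >= 1 hydrogen
  HBA:
    enabled: true            # N/O not carrying a positive formal charge
  aromatic_ring:
    enabled: true            # each independent ring of the aromatic system
  hydrophobic:
    enabled: true
    min_atoms: 3             # maximal carbon-only subgraph size threshold
  pos_ionizable:
    enabled: true
    patterns:
      - aliphatic_amine      # non-amide, non-sulfonamide sp3 amine N
  neg_ionizable:
    enabled: true
    patterns:
      - carboxylic_acid      # C(=O)OH / carboxylate
      - sulfonic_acid        # S(=O)(=O)OH
      - sulfonamide_nh       # N-H on a sulfonyl S
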