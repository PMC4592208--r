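Package: hdacScreen
Title: QSAR-Based Virtual Screening and Ligand-Efficiency Prioritization
    for HDAC Inhibitor Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for 2D QSAR-driven virtual screening of small-molecule
    libraries against class I histone deacetylases (HDAC1/2/3/8).
    Implements an annotated molecular-graph container with SMILES and SDF
    V2000 readers, topological descriptor calculators (Balaban J index,
    fragment-additive topological polar surface area, atom-additive logP
    and molar polarizability, hydrogen-bond donor/acceptor counts),
    multiple linear regression machinery for pIC50 models with classical
    forward/backward/stepwise descriptor selection, a frozen published
    five-descriptor activity model, active/decoy screen validation
    statistics (sensitivity, specificity, percent yield, enrichment
    factor, Guner-Henry score), a 2D feature-count pharmacophore
    surrogate for library ranking, the ligand-efficiency prioritization
    suite (LE, LEScale, LipE, FQ) with Rule-of-Five filtering, and a
    seeded synthetic compound/activity generator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), ChemmineR, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
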