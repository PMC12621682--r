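Package: natk
Title: Nucleic Acid Design Templating and Evaluation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for specifying, encoding, constructing and screening nucleic
    acid structural designs. Parses and writes pseudoknotted dot-bracket
    secondary structures with arbitrary bracket order and multi-chain records;
    encodes three-channel base-pair conditioning tensors with region-level
    parallel/antiparallel orientation control and multi-chain strand-exchange
    topologies; generates symmetric single-chain pseudocycle templates from
    graph-level topology specifications with randomized length diversification;
    builds full-atom RNA and DNA sugar-phosphate backbones from per-residue
    frames and torsion angles by internal-coordinate propagation, including
    ideal A-/B-form duplex fixtures; and evaluates designs with base-pair F1
    scores, Kabsch superposition RMSD, length-normalized TM-scores, alignment
    coverage, simulated chemical-probing (SHAPE) reactivity concordance, and
    threshold filtering of design records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
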