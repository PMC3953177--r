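Package: evodecoy
Title: Evolutionary and Memetic Decoy Sampling for De Novo Protein Structure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-based evolutionary search over coarse-grained protein
    conformations for first-stage (decoy) sampling in de novo structure
    prediction. Conformations are represented by backbone dihedral angles
    under an idealized-geometry kinematic model; child conformations are
    generated by molecular fragment replacement from 3-mer fragment
    configuration libraries, and survival is decided by truncation selection
    on a pluggable coarse-grained energy. A basic evolutionary algorithm and
    a memetic variant (each child mapped to a nearby local minimum by greedy
    fragment-replacement descent) are provided, together with a five-term
    backbone energy, Kabsch least-RMSD, decoy-ensemble analytics (lowest
    lRMSD summaries, 95th-percentile energy reduction, pairwise-lRMSD
    diversity), a synthetic toybox with planted targets for offline testing,
    and PDB/FASTA/fragment-library input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    bio3d,
    seqinr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
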