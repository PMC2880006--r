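Package: pepdesign
Title: De Novo Peptide Design by RIS Chain Statistics and Viterbi Decoding
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs peptide sequences against a protein surface from
    per-grid docking energies. Single-residue and dipeptide binding
    energies along a path of grid boxes are converted to Boltzmann
    statistical weights; a rotational-isomeric-state (RIS) transfer-matrix
    scheme yields the chain partition function, pairwise residue marginals
    and conditional transition probabilities; backbone torsion-angle
    observations of the docked candidates are classified into eleven
    Ramachandran states whose coil-library propensities act as emission
    probabilities; and a log-space Viterbi algorithm decodes the
    highest-probability peptide sequence. Includes readers for energy
    tables, docking logs and coil libraries, grid-box construction from
    PDB structures, a synthetic fixture generator with planted optima,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
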