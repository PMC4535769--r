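Package: groovedyn
Title: Conformational and Energetic Analysis of MHC Class I Peptide-Binding Grooves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how peptide ligands stabilize the
    binding groove of major histocompatibility complex (MHC) class I molecules.
    Provides ensemble statistics over coordinate trajectories (Kabsch
    superposition, RMSD series and distributions, per-residue RMSF profiles,
    groove width variance over helix regions, leader clustering with a
    convergence diagnostic), MM-PBSA-style binding free-energy aggregation with
    cluster-based uncertainties and delta-delta-G ranking, potentials of mean
    force from umbrella-sampling windows via the weighted histogram analysis
    method (WHAM), experimental curve fits (two-state thermal denaturation,
    four-parameter logistic IC50 competition, exponential surface decay), a
    cross-method delta-delta-G correlation report, and synthetic-data
    generators with known ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
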