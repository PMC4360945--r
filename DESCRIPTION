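Package: vsfunnel
Title: Hierarchical Virtual-Screening Funnel with Consensus Voting and
    Pose-Consistency RMSD
Version: 0.1.0
Authors@R:
    person("VPC", "Screening", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A structure-based virtual-screening triage pipeline: staged
    docking-score threshold filters, a cross-program pose-consistency
    filter based on symmetry-corrected in-place heavy-atom RMSD, and a
    top-decile binary consensus vote over multiple scoring criteria.
    Includes a seeded synthetic screening-library generator (correlated
    criterion scores with planted binders, and perturbed pose pairs)
    so every stage is testable without commercial docking engines, plus
    readers and writers for CSV score tables, multi-record SDF V2000
    pose files with SD score tags, and ranked hit lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
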