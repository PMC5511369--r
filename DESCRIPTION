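Package: clonecircuit
Title: Electrical and Chemical Synapse Detection in Clonally Related
    Interneuron Recordings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of multi-cell patch-clamp experiments
    probing gap-junction (electrical) and GABAergic (chemical) synapses
    between neocortical interneurons. Provides a ground-truth circuit
    simulator with the standard paired-recording stimulation protocol,
    extraction of the nine membrane and firing features used to classify
    fast-spiking interneurons, amplitude-criterion connection detection
    with coupling-coefficient estimation, Z-scored spike-train
    cross-correlograms with a 3-SD peak rule, spatial statistics of
    labelled clonal point patterns (nearest-neighbour-distance CDFs,
    intra- versus interclonal distances, linkage dendrograms), and
    contingency-table statistics over pair cohorts including a transcribed
    table of published pair counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
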