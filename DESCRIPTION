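Package: axonperm
Title: Hydraulic Permeability of White Matter from Axon-Scale Microstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the hydraulic permeability of brain white matter from
    its axon-scale geometry. Generates random, highly packed planar disc
    assemblies that honour a target axon diameter distribution, extracellular
    space (ECS) volume fraction and ECS width; verifies the spatial
    randomness of the packing with Ripley's R and L functions; solves steady
    creeping (Stokes) flow through the extracellular space of a channel
    containing the packing; and homogenises the velocity and pressure fields
    to a Darcy permeability over nested square windows, selecting the
    representative volume element (RVE) size at which the permeability
    estimate stabilises across replicate geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    spatial,
    optparse
Config/testthat/edition: 3
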