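Package: dropletpix
Title: Simulation and Compilation Toolkit for Droplet Pixel Arrays
Version: 0.1.0
Authors@R:
    person("Dropletpix", "Developers", email = "dropletpix@example.org",
           role = c("aut", "cre"))
Description: Computational layer of a desk-scale droplet-microfluidics
    workflow: synthetic photomultiplier (PMT) trace generation for droplet
    transits past multiple laser excitation points, a streaming peak
    detector with a drift-free adaptive baseline, grouping of per-laser
    peaks into droplet fluorescence signatures, k-means and threshold
    classification onto an 8-color high/low RGB palette, empirically
    parameterized surrogate models of microfluidic components (droplet
    generation envelope, Poisson single-cell encapsulation, picoinjection
    volume change, dielectrophoretic sorting regimes, anchor trapping),
    an image-to-droplet "pixel array" compiler (palette quantization,
    5x5 tiling, unique-pattern decomposition, sort-instruction generation
    that inverts serpentine anchor FIFO dynamics, mosaic stitching), and
    an end-to-end stochastic workflow simulator with injectable fault
    modes for verification studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    yaml
Config/testthat/edition: 3
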