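Package: palmcount
Title: Single-Molecule Counting, Stoichiometry and Mobility Analysis for
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of photoactivated localization microscopy
    (PALM) data for absolute molecule counting: spot localization with 2D
    Gaussian fitting and fiducial-based drift correction, density filtering
    and cluster selection of detections, burst segmentation with a bleaching
    time cutoff, binomial inference of subunit stoichiometry with
    missed-event (zero-burst) correction, conversion of detection counts
    into absolute molecule and complex numbers and 2D densities at synapses,
    intensity correlation quotient colocalization, and mean-square
    displacement analysis of single-particle tracking trajectories. A
    ground-truthed photophysics simulator generates localization tables,
    image stacks, trajectories and two-channel images so that every stage of
    the pipeline can be validated without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
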