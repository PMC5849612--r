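Package: wingbeam
Title: Cross-Sectional Wing-Bone Geometry and Phylogenetic Classification of
    Archosaur Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers locomotor and flight modes of archosaurs from the
    cross-sectional geometry of their wing bones. Computes beam-theory
    section properties (cortical and total subperiosteal area, second
    moments of area, polar moment J) and cortical vascular density from
    binary or grayscale section rasters; reconstructs body masses of
    extinct taxa from skeletal measurements through allometric relations;
    and runs a phylogenetically informed multivariate classification
    chain: phylogenetic PCA under Brownian motion, k-medoids and k-means
    clustering of volancy, Pagel's lambda screening, linear discriminant
    classification of avian flight modes, simulation-based phylogenetic
    ANCOVA, and one-way MANOVA. Includes a synthetic-data generator that
    produces analytic-ground-truth section rasters and archosaur-like
    trait tables with Brownian-motion structure on a chronogram, so the
    whole chain is testable without fossil material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    cluster,
    MASS,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
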