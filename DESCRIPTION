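Package: fibos
Title: Occluded Surface Packing Analysis of Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes atomic packing density in protein structures with the
    occluded surface (OS) method: van der Waals spheres are covered with
    area-carrying surface dots, each dot's outward normal is traced until it
    meets a neighboring atom's van der Waals surface or exceeds the diameter
    of a water molecule, and the occluded areas and normal lengths are
    aggregated into the occluded surface packing density (OSP) per atom,
    residue and structure. Dots are placed either with the classical
    axis-referenced radial lattice or with a Fibonacci golden-angle spiral
    (the default), which spaces points more evenly over the sphere. Includes
    a paired-comparison stage for two conformers of the same chain (paired
    Wilcoxon signed-rank test, Cohen's d, and jackknife influence screening
    of residues driving dispersion differences), synthetic sphere-cluster
    fixtures with a brute-force occlusion oracle, and command-line entry
    points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
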