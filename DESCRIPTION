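Package: morphosym
Title: Object Symmetry and Asymmetry Analysis of Outline Semilandmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric morphometrics of bilaterally symmetric outlines
    sampled as semilandmarks, aimed at repeated modules (such as the
    calcified segments of siphonous green algae) digitized in a nested
    sampling design. Provides generalized Procrustes superimposition with
    three semilandmark treatments (unslid equidistant points, sliding to
    minimum thin-plate-spline bending energy, sliding to minimum
    Procrustes distance), decomposition of object symmetry into symmetric
    variation, directional asymmetry and fluctuating asymmetry,
    multivariate regression of shape on centroid size with a permutation
    test of Wilks' lambda, nested Procrustes ANOVA with
    design-appropriate F ratios and restricted permutations, per-plant
    variance decompositions with bootstrap population comparisons, a
    total shape-asymmetry statistic, TPS and plain-text coordinate I/O,
    and a hierarchical synthetic outline generator for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
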