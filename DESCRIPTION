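Package: morphoridge
Title: Morphoelastic Modelling of Hierarchical Ridge and Spine Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced 'Gaussian bumps' model of hierarchical wrinkling on a
    growing two-layer elastic system, motivated by the spiral ridge and spine
    ornamentation of mollusc shells. The deformed interface is represented as a
    sum of separated Gaussian bumps whose widths, amplitudes and bifurcation
    times follow from quasi-static minimization of a reduced bending plus
    foundation-interaction energy under an excess-length constraint. Includes
    recursive intercalation of higher hierarchical levels on the expanding
    domain, foundation remodelling (memory) dynamics, burst-growth dilation of
    ridges into linear or fractal-like spines with an energy comparison of the
    two pathways, a direct functional-minimization oracle for validating the
    separated-Gaussian reduction, and surface generation with OBJ/PLY export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
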