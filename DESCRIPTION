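Package: slicemesh
Title: Watertight Surface Meshes from Serial Planar Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reconstructs watertight 3D triangle meshes from ordered stacks
    of parallel closed 2D contours, such as slice-wise bone segmentations
    from CT. The surface band between each pair of consecutive contours is
    triangulated by minimising total triangle area with a dynamic program
    over the span graph of the two rings, after optional contour
    normalisation, branching resolution (bridging co-planar contours at
    their nearest points) and keyhole removal. The first and last contours
    are sealed with planar cap triangulations, and the assembled mesh can be
    validated for watertightness and written as STL, PLY or OBJ. A
    deterministic fixture generator provides synthetic contour stacks
    (cylinders, cones, branches, keyhole shapes) for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
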