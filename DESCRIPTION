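Package: puzzlecell
Title: Simulation and Shape Analysis of Puzzle-Shaped Epidermal Pavement Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how jigsaw-puzzle-shaped pavement cells emerge
    in plant epidermis. Provides a geometric-mechanical tissue simulator in
    which polygonal cells grow under imposed (an)isotropic tissue expansion
    while tension-only transversal springs -- a proxy for stress-responsive,
    microtubule-guided cellulose reinforcement -- locally restrict growth and
    generate lobes. Also implements the standard contour-based shape
    statistics used for pavement cells: lobeyness (perimeter over convex-hull
    perimeter), circularity, convex-hull solidity, the largest empty circle
    computed from a Delaunay triangulation of the contour, principal-plane
    projection of 3D contours, growth-anisotropy estimation from tracked
    contours and a thin-wall hoop-stress proxy. All inputs and outputs are
    plain data frames so analyses compose with the tidyverse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    grDevices,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
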