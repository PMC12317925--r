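Package: costwalk
Title: Cellular-Automata Least-Cost Walks on Cost Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of movement across a georeferenced
    cost (friction) surface using a cellular-automata transition rule:
    at each timestep the agent relocates to the minimum-mean-cost cell
    of a single-ring square (Moore) or hexagonal neighbourhood, with
    random tie-breaking and exclusion of previously visited cells.
    Includes batch orchestration of seeded walks, walk-density
    rasterisation, per-walk distance and deviation statistics,
    quadrant-method azimuths, circular uniformity tests (Rayleigh and
    Stephens-modified Kuiper), rose-diagram binning, synthetic cost
    surface generators, Horn slope estimation from elevation models,
    Esri ASCII grid raster I/O, GeoJSON walk export, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
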