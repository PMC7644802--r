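Package: modcad
Title: Coarse-Grained Design of Modular Protein Architectures
Version: 0.1.0
Authors@R:
    person("Avery", "Moss", email = "avery.moss@example.org", role = c("aut", "cre"))
Description: Headless toolkit for designing large protein architectures from
    libraries of compatible structural building blocks (repeat-protein core
    modules, junctions, oligomeric hubs and capping repeats).  Provides
    rigid-body transform algebra and Kabsch superposition, construction and
    validation of a JSON module database with pairwise interface transforms,
    an editable design scene with compatibility-filtered extrusion,
    mirror-linked symmetric growth, network bookkeeping and sphere-based
    clash detection, geometry-only path guides for shape-directed automated
    design, a deterministic reference solver, and conversion of coarse-grained
    designs into capped all-atom models written as mmCIF.  Includes a fully
    synthetic toy module library with analytic ground truth so that the whole
    pipeline can be exercised without any external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
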