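Package: topostrings
Title: Protein Topology Strings from Secondary-Structure Contact Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives a canonical one-dimensional "topology string" for a
    protein chain from the contact adjacency matrix of its secondary-structure
    elements, extracts the chain's constituent topological modules, maintains
    a topology database with occurrence statistics and Prevalent/Non-prevalent
    classification under false-discovery-rate control, and renders linear,
    contact-map and 2D-cartoon topology diagrams as SVG. Includes a built-in
    simplified Kabsch-Sander secondary-structure assigner, a DSSP-file import
    path, and generators for synthetic chains of ideal helices and strands
    with known ground-truth topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
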