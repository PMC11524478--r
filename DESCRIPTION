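Package: panelprov
Title: Provenance Analysis of Scientific Figure Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks reuse and manipulation of figure panels across collections
    of scientific documents. Extracts figure rasters from PDFs or image
    directories, locates panels within compound figures, computes
    transformation-robust panel descriptors with top-K cosine retrieval,
    verifies candidate pairs with SIFT-style interest-point matching and a
    robust homography fit (with mirrored retry), scores shared content as the
    convex-hull area fraction of the verified matches, and assembles
    image-level and document-level provenance graphs (connected components and
    maximum spanning trees). Includes the content pairing, grouping and
    classification evaluation metrics and a deterministic synthetic-corpus
    generator with planted cross-document panel reuse for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    Rcpp,
    png,
    jsonlite,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jpeg,
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
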