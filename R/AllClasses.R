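#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib panelprov, .registration = TRUE
NULL

#' FigureImage: one figure raster extracted from a source document
#'
#' @slot figureId character, unique id of the form "<doc_id>/fig<k>".
#' @slot docId character, id of the owning document.
#' @slot raster numeric array h x w x 3 with values in [0, 1].
#' @export
setClass("FigureImage",
  representation(figureId = "character", docId = "character", raster = "array"))

setValidity("FigureImage", function(object) {
  d <- dim(object@raster)
  if (length(d) != 3L || d[3] != 3L) return("raster must be an h x w x 3 array")
  if (d[1] < 1L || d[2] < 1L) return("raster must have width >= 1 and height >= 1")
  TRUE
})

#' Panel: a typed, cropped sub-image of a figure
#'
#' Panels are the unit of provenance analysis: each is a rectangular crop of a
#' compound figure, labelled with one of the five panel types of interest.
#'
#' @slot panelId character "<figure_id>/p<k>".
#' @slot docId,figureId provenance back-pointers.
#' @slot bbox numeric length 4: (x_min, y_min, x_max, y_max), 0-based pixel
#'   coordinates, half-open on the max edges.
#' @slot panelType one of "microscopy", "blots", "body_imaging",
#'   "graphs_plots", "flow_cytometry", "unknown".
#' @slot raster numeric array h x w x 3 in [0, 1]; dimensions equal the bbox.
#' @export
setClass("Panel",
  representation(panelId = "character", docId = "character",
                 figureId = "character", bbox = "numeric",
                 panelType = "character", raster = "array"))

PANEL_TYPES <- c("microscopy", "blots", "body_imaging", "graphs_plots",
                 "flow_cytometry", "unknown")

setValidity("Panel", function(object) {
  d <- dim(object@raster)
  if (length(d) != 3L || d[3] != 3L) return("raster must be an h x w x 3 array")
  if (length(object@bbox) != 4L) return("bbox must have 4 entries")
  b <- object@bbox
  if (b[1] < 0 || b[2] < 0 || b[3] <= b[1] || b[4] <= b[2])
    return("bbox must satisfy 0 <= x_min < x_max, 0 <= y_min < y_max")
  if (d[2] != b[3] - b[1] || d[1] != b[4] - b[2])
    return("raster dimensions must equal bbox dimensions")
  if (!object@panelType %in% PANEL_TYPES)
    return(paste("panelType must be one of:", paste(PANEL_TYPES, collapse = ", ")))
  TRUE
})

#' EvidenceDB: panel descriptors with metadata for similarity retrieval
#'
#' @slot vectors numeric matrix, one L2-normalized descriptor per row,
#'   rownames are panel ids.
#' @slot meta data.frame with columns panel_id, doc_id, panel_type.
#' @slot backend character, name of the descriptor backend.
#' @export
setClass("EvidenceDB",
  representation(vectors = "matrix", meta = "data.frame", backend = "character"))

setValidity("EvidenceDB", function(object) {
  if (nrow(object@vectors) != nrow(object@meta))
    return("one metadata row per descriptor required")
  if (!identical(rownames(object@vectors), object@meta$panel_id))
    return("descriptor rownames must equal meta$panel_id")
  if (nrow(object@vectors) > 0) {
    nrm <- sqrt(rowSums(object@vectors^2))
    if (any(abs(nrm - 1) > 1e-6)) return("descriptors must be L2-normalized")
  }
  TRUE
})

#' RetrievalConfig: tunable parameters of the provenance workflow
#'
#' Defaults follow the reference operating point: top-K retrieval K = 400,
#' queue expansion L = 40, per-probe queue budget 300, content-sharing score
#' threshold 0.01 (1%), and a minimum of 20 consistent matches for a pair to
#' be considered consistent.
#'
#' @slot K integer, retrieval depth for the initial processing queue.
#' @slot L integer (L <= K), expansion depth when a suspicious pair is found.
#' @slot queueCap integer, panels examined per probe before the loop stops.
#' @slot scoreThreshold numeric, inclusive threshold on directional scores.
#' @slot minInliers integer, minimum consistent matches.
#' @slot ratio numeric, Lowe ratio for descriptor matching.
#' @slot reprojTol numeric, robust-fit reprojection tolerance in pixels.
#' @slot maxIter integer, robust-fit iteration cap.
#' @slot seed integer, base seed for the robust fit's sampler.
#' @slot flipAxis "horizontal" or "vertical" mirror retry.
#' @export
setClass("RetrievalConfig",
  representation(K = "integer", L = "integer", queueCap = "integer",
                 scoreThreshold = "numeric", minInliers = "integer",
                 ratio = "numeric", reprojTol = "numeric", maxIter = "integer",
                 seed = "integer", flipAxis = "character"),
  prototype(K = 400L, L = 40L, queueCap = 300L, scoreThreshold = 0.01,
            minInliers = 20L, ratio = 0.75, reprojTol = 3, maxIter = 2000L,
            seed = 20210L, flipAxis = "horizontal"))

setValidity("RetrievalConfig", function(object) {
  if (object@K < 1L || object@L < 1L || object@L > object@K)
    return("need 1 <= L <= K")
  if (object@queueCap < 1L) return("queueCap must be positive")
  if (object@minInliers < 1L) return("minInliers must be positive")
  if (!object@flipAxis %in% c("horizontal", "vertical"))
    return("flipAxis must be 'horizontal' or 'vertical'")
  TRUE
})

#' Constructor for RetrievalConfig
#'
#' @param K,L,queueCap,scoreThreshold,minInliers,ratio,reprojTol,maxIter,seed,flipAxis
#'   see the class slots.
#' @return a RetrievalConfig object.
#' @export
retrievalConfig <- function(K = 400L, L = 40L, queueCap = 300L,
                            scoreThreshold = 0.01, minInliers = 20L,
                            ratio = 0.75, reprojTol = 3, maxIter = 2000L,
                            seed = 20210L, flipAxis = "horizontal") {
  new("RetrievalConfig", K = as.integer(K), L = as.integer(L),
      queueCap = as.integer(queueCap), scoreThreshold = scoreThreshold,
      minInliers = as.integer(minInliers), ratio = ratio,
      reprojTol = reprojTol, maxIter = as.integer(maxIter),
      seed = as.integer(seed), flipAxis = flipAxis)
}

#' MatchResult: verified correspondences between two panels
#'
#' @slot panelP,panelR the panel ids of the pair.
#' @slot inlierP,inlierR n x 2 matrices of corresponding (x, y) coordinates in
#'   each panel's own frame (P-side coordinates are always in the unflipped
#'   frame, even when the match used the mirrored panel).
#' @slot homography 3 x 3 matrix mapping P-frame coordinates to R-frame.
#' @slot mirrored logical, TRUE when the match succeeded on the flipped panel.
#' @slot consistent logical, TRUE when at least minInliers survived.
#' @export
setClass("MatchResult",
  representation(panelP = "character", panelR = "character",
                 inlierP = "matrix", inlierR = "matrix",
                 homography = "matrix", mirrored = "logical",
                 consistent = "logical"))

#' ContentSharedTable: sparse panel-level directional score table
#'
#' Cell (P, R) holds the content-sharing score of P with respect to R; the two
#' directions of a pair are always written together. The processed-pair
#' registry records every examined pair (including inconsistent ones) so a
#' pair is never analyzed twice.
#'
#' @slot entries data.frame(row_id, col_id, score).
#' @slot processed character vector of canonical pair keys.
#' @export
setClass("ContentSharedTable",
  representation(entries = "data.frame", processed = "character"),
  prototype(entries = data.frame(row_id = character(), col_id = character(),
                                 score = numeric(), stringsAsFactors = FALSE),
            processed = character()))

#' ProvenanceGraph: a component or spanning tree of linked panels/documents
#'
#' @slot nodes character vector of node ids.
#' @slot edges data.frame(from, to, weight).
#' @slot nodeMeta data.frame of per-node attributes (doc_id, figure_id), may
#'   be empty.
#' @slot isTree logical, TRUE for a maximum spanning tree.
#' @slot level "image" or "document".
#' @export
setClass("ProvenanceGraph",
  representation(nodes = "character", edges = "data.frame",
                 nodeMeta = "data.frame", isTree = "logical",
                 level = "character"),
  prototype(nodeMeta = data.frame(), isTree = FALSE, level = "image"))

#' DocumentMatrix: n x n shared-element counts between documents
#'
#' @slot counts symmetric integer matrix with doc ids as dimnames and a zero
#'   diagonal; cell (i, j) counts the suspicious panel pairs shared by
#'   documents i and j.
#' @export
setClass("DocumentMatrix", representation(counts = "matrix"))

setValidity("DocumentMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (!identical(rownames(m), colnames(m))) return("dimnames must agree")
  if (any(m != t(m))) return("matrix must be symmetric")
  if (any(diag(m) != 0)) return("diagonal must be zero")
  if (any(m < 0)) return("counts must be non-negative")
  TRUE
})

#' MetricsReport: content pairing / grouping / classification metrics
#'
#' @slot level "image" or "document".
#' @slot values named numeric vector with entries LP, LR, CP, NP, NR, CG,
#'   precision, recall, CC (all in [0, 1]).
#' @export
setClass("MetricsReport",
  representation(level = "character", values = "numeric"))

#' @describeIn Panel-class compact display
#' @param object a Panel
#' @export
setMethod("show", "Panel", function(object) {
  d <- dim(object@raster)
  cat(sprintf("Panel '%s' [%s] %dx%d px (doc %s)\n", object@panelId,
              object@panelType, d[2], d[1], object@docId))
})

setMethod("show", "FigureImage", function(object) {
  d <- dim(object@raster)
  cat(sprintf("FigureImage '%s' %dx%d px (doc %s)\n", object@figureId,
              d[2], d[1], object@docId))
})

setMethod("show", "EvidenceDB", function(object) {
  cat(sprintf("EvidenceDB: %d panels, %d-d '%s' descriptors, %d documents\n",
              nrow(object@vectors), ncol(object@vectors), object@backend,
              length(unique(object@meta$doc_id))))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult %s ~ %s: %s (%d inliers%s)\n", object@panelP,
              object@panelR, if (object@consistent) "consistent" else "inconsistent",
              nrow(object@inlierP), if (object@mirrored) ", mirrored" else ""))
})

setMethod("show", "ContentSharedTable", function(object) {
  cat(sprintf("ContentSharedTable: %d cells (%d pairs), %d pairs examined\n",
              nrow(object@entries), nrow(object@entries) %/% 2L,
              length(object@processed)))
})

setMethod("show", "ProvenanceGraph", function(object) {
  cat(sprintf("%s-level provenance %s: %d nodes, %d edges\n", object@level,
              if (object@isTree) "tree" else "component",
              length(object@nodes), nrow(object@edges)))
})

setMethod("show", "DocumentMatrix", function(object) {
  cat(sprintf("DocumentMatrix: %d documents, %d shared-element pairs\n",
              nrow(object@counts), sum(object@counts > 0) %/% 2L))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%s level)\n", object@level))
  print(round(object@values, 4))
})
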