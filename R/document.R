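#' Aggregate panel-level evidence into the document matrix
#'
#' Builds the n x n symmetric matrix M over all documents of the corpus:
#' cell (i, j) counts the suspicious panel pairs (content-shared table pairs
#' whose larger directional score reaches the threshold) between documents i
#' and j. The diagonal is zero by construction: same-document pairs are never
#' analyzed.
#'
#' @param table a \linkS4class{ContentSharedTable}.
#' @param panelMeta data.frame with columns panel_id and doc_id covering
#'   every panel in the table (e.g. the `meta` of an
#'   \linkS4class{EvidenceDB}); a table panel absent from it is a
#'   data-integrity error.
#' @param threshold inclusive score threshold (default 0.01).
#' @return a \linkS4class{DocumentMatrix} with sorted doc-id dimnames.
#' @export
buildDocumentMatrix <- function(table, panelMeta, threshold = 0.01) {
  if (is(panelMeta, "EvidenceDB")) panelMeta <- panelMeta@meta
  docs <- sort(unique(panelMeta$doc_id))
  m <- matrix(0L, length(docs), length(docs), dimnames = list(docs, docs))
  edges <- suspiciousEdges(table, threshold)
  if (nrow(edges) > 0) {
    di <- panelMeta$doc_id[match(edges$from, panelMeta$panel_id)]
    dj <- panelMeta$doc_id[match(edges$to, panelMeta$panel_id)]
    if (anyNA(di) || anyNA(dj)) {
      bad <- unique(c(edges$from[is.na(di)], edges$to[is.na(dj)]))
      stop("panels with unknown source document: ",
           paste(bad, collapse = ", "))
    }
    for (k in seq_along(di)) {
      m[di[k], dj[k]] <- m[di[k], dj[k]] + 1L
      m[dj[k], di[k]] <- m[dj[k], di[k]] + 1L
    }
  }
  new("DocumentMatrix", counts = m)
}

#' Document-level provenance components and spanning trees
#'
#' Links two documents when they share at least one suspicious panel pair
#' (d_ij >= 1), finds the connected components, and prunes each to its
#' maximum spanning tree on the integer shared-element counts (same
#' tie-breaking as the image level). Documents with no suspicious pair do
#' not appear in any graph.
#'
#' @param M a \linkS4class{DocumentMatrix}.
#' @return list(components = ..., trees = ...) of document-level
#'   \linkS4class{ProvenanceGraph} objects.
#' @export
documentGraphs <- function(M) {
  m <- M@counts
  idx <- which(upper.tri(m) & m >= 1, arr.ind = TRUE)
  edges <- data.frame(from = rownames(m)[idx[, 1]],
                      to = colnames(m)[idx[, 2]],
                      weight = as.numeric(m[idx]), stringsAsFactors = FALSE)
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  comps <- componentsFromEdges(edges, level = "document")
  list(components = comps, trees = lapply(comps, maximumSpanningTree))
}

#' Serialize a document matrix as CSV with doc-id headers
#'
#' @param M a \linkS4class{DocumentMatrix}.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
writeDocumentMatrix <- function(M, path) {
  utils::write.csv(as.data.frame(M@counts), path, row.names = TRUE)
  invisible(path)
}
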