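#' Create an empty content-shared table
#'
#' @return a \linkS4class{ContentSharedTable} with no entries.
#' @export
contentSharedTable <- function() new("ContentSharedTable")

#' Look up the directional score of a cell
#'
#' @param table a \linkS4class{ContentSharedTable}.
#' @param row,col panel ids; the cell (row, col) holds the score of `row`
#'   with respect to `col`.
#' @return the score, or NA when the pair was not recorded.
#' @export
tableScore <- function(table, row, col) {
  hit <- table@entries$row_id == row & table@entries$col_id == col
  if (any(hit)) table@entries$score[which(hit)[1]] else NA_real_
}

# write both directional cells of a pair
tableWritePair <- function(table, P, R, scorePR, scoreRP) {
  table@entries <- rbind(table@entries,
                         data.frame(row_id = c(P, R), col_id = c(R, P),
                                    score = c(scorePR, scoreRP),
                                    stringsAsFactors = FALSE))
  table
}

# keypoint cache: avoids re-extracting interest points across probes
kpCacheGet <- function(cache, id, panels, flipped = FALSE, axis = "horizontal") {
  key <- if (flipped) paste0(id, "||flip") else id
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  kp <- if (flipped) extractKeypoints(flipRaster(panels[[id]]@raster, axis))
        else extractKeypoints(panels[[id]])
  if (!is.null(cache)) cache[[key]] <- kp
  kp
}

#' Run the provenance processing-queue loop for one probe panel
#'
#' The queue is initialized with the top-K panels most similar to the probe
#' (same type, other documents). Panels are dequeued FIFO; each candidate not
#' previously examined against the probe is verified with
#' [matchAndVerify()], and — when consistent — the two directional
#' content-sharing scores are written into the table. If either directional
#' score reaches the threshold, the queue is expanded with the top-L panels
#' most similar to the candidate (same type restriction, excluding the
#' probe's document, deduplicated against the queue and the processed set).
#' The loop ends when the queue empties or `queueCap` panels have been
#' examined for this probe (inconsistent candidates count toward the budget).
#'
#' @param probe panel id of P.
#' @param panels named list of \linkS4class{Panel}.
#' @param db an \linkS4class{EvidenceDB} over the same panels.
#' @param table the \linkS4class{ContentSharedTable} to update (its processed
#'   registry may be shared across probes).
#' @param cfg a \linkS4class{RetrievalConfig}.
#' @param cache optional environment caching interest points across calls.
#' @return the updated table.
#' @export
processProbe <- function(probe, panels, db, table = contentSharedTable(),
                         cfg = retrievalConfig(), cache = NULL) {
  stopifnot(probe %in% db@meta$panel_id)
  P <- panels[[probe]]
  queue <- retrieveSimilar(probe, db, k = cfg@K)$panel_id
  queued <- queue
  examined <- 0L
  while (length(queue) > 0 && examined < cfg@queueCap) {
    RI <- queue[1]
    queue <- queue[-1]
    key <- pairKey(probe, RI)
    if (key %in% table@processed) next
    examined <- examined + 1L
    table@processed <- c(table@processed, key)
    kpP <- kpCacheGet(cache, probe, panels)
    kpR <- kpCacheGet(cache, RI, panels)
    kpF <- if (is.null(cache)) NULL
           else kpCacheGet(cache, probe, panels, flipped = TRUE,
                           axis = cfg@flipAxis)
    m <- matchAndVerify(P, panels[[RI]], cfg, kpP = kpP, kpR = kpR,
                        kpPFlip = kpF)
    if (!m@consistent) next
    sc <- contentSharingScore(m, P, panels[[RI]])
    table <- tableWritePair(table, probe, RI,
                            sc[["score_P_given_R"]], sc[["score_R_given_P"]])
    if (max(sc) >= cfg@scoreThreshold) {
      nbrs <- retrieveSimilar(RI, db, k = cfg@L)$panel_id
      nbrs <- nbrs[nbrs != probe &
                     db@meta$doc_id[match(nbrs, db@meta$panel_id)] != P@docId]
      nbrs <- nbrs[!(nbrs %in% queued) &
                     !(pairKey(probe, nbrs) %in% table@processed)]
      queue <- c(queue, nbrs)
      queued <- c(queued, nbrs)
    }
  }
  table
}

#' Build the full content-shared table for a corpus
#'
#' Runs [processProbe()] for every panel in sorted panel-id order with a
#' shared processed-pair registry, so each unordered pair is examined at most
#' once globally. Deterministic: identical inputs yield identical tables.
#'
#' @inheritParams processProbe
#' @param progress print one line per probe.
#' @return a \linkS4class{ContentSharedTable}.
#' @export
buildSharedTable <- function(panels, db, cfg = retrievalConfig(),
                             progress = FALSE) {
  table <- contentSharedTable()
  cache <- new.env(parent = emptyenv())
  for (probe in sort(db@meta$panel_id)) {
    if (progress) message("probe ", probe)
    table <- processProbe(probe, panels, db, table, cfg, cache)
  }
  ord <- order(table@entries$row_id, table@entries$col_id)
  table@entries <- table@entries[ord, , drop = FALSE]
  rownames(table@entries) <- NULL
  table@processed <- sort(table@processed)
  table
}

# undirected suspicious edges: max of the two directional scores >= threshold
suspiciousEdges <- function(table, threshold) {
  e <- table@entries
  if (nrow(e) == 0)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  a <- pmin(e$row_id, e$col_id); b <- pmax(e$row_id, e$col_id)
  key <- paste(a, b, sep = "||")
  w <- tapply(e$score, key, max)
  keep <- w >= threshold
  if (!any(keep))
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  parts <- strsplit(names(w)[keep], "||", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[`, character(1), 1),
                    to = vapply(parts, `[`, character(1), 2),
                    weight = as.numeric(w[keep]), stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Undirected suspicious links of a content-shared table
#'
#' A pair is linked when the larger of its two directional scores reaches
#' the threshold (inclusive).
#'
#' @param table a \linkS4class{ContentSharedTable}.
#' @param threshold score threshold (default 0.01).
#' @return data.frame(from, to, weight) with from < to.
#' @export
tableLinks <- function(table, threshold = 0.01) {
  suspiciousEdges(table, threshold)
}

#' Connected components of the content-shared table
#'
#' Links all pairs whose content-sharing score reaches the threshold and
#' isolates the resulting groups (connected components). Components are
#' returned sorted by size (descending), then by their lexicographically
#' smallest node.
#'
#' @param table a \linkS4class{ContentSharedTable}.
#' @param threshold inclusive score threshold (default 0.01).
#' @param nodeMeta optional data.frame with a `panel_id` column (plus e.g.
#'   doc_id, figure_id) attached to each graph.
#' @param level graph level label ("image" or "document").
#' @return list of \linkS4class{ProvenanceGraph} (components, not trees).
#' @export
provenanceComponents <- function(table, threshold = 0.01, nodeMeta = NULL,
                                 level = "image") {
  edges <- if (is.data.frame(table)) table else suspiciousEdges(table, threshold)
  componentsFromEdges(edges, nodeMeta, level)
}

componentsFromEdges <- function(edges, nodeMeta = NULL, level = "image") {
  if (nrow(edges) == 0) return(list())
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1))
  lapply(unname(groups[ord]), function(nodes) {
    sub <- edges[edges$from %in% nodes & edges$to %in% nodes, , drop = FALSE]
    rownames(sub) <- NULL
    meta <- if (is.null(nodeMeta)) data.frame()
            else nodeMeta[nodeMeta$panel_id %in% nodes, , drop = FALSE]
    new("ProvenanceGraph", nodes = nodes, edges = sub, nodeMeta = meta,
        isTree = FALSE, level = level)
  })
}

#' Maximum spanning tree of a provenance component
#'
#' Prunes the component to the acyclic subgraph that maximizes the sum of
#' content-sharing scores (Kruskal on descending weights; ties broken by the
#' lexicographically smaller (from, to) edge, so results are identical across
#' runs and platforms). The node of highest degree in the tree is the
#' suspected hub of the reuse group (see [nodeDegrees()]).
#'
#' @param component a connected \linkS4class{ProvenanceGraph}.
#' @return a \linkS4class{ProvenanceGraph} with `isTree = TRUE` and |V|-1
#'   edges.
#' @export
maximumSpanningTree <- function(component) {
  stopifnot(is(component, "ProvenanceGraph"))
  e <- component@edges
  nodes <- component@nodes
  if (nrow(e) <= 1 || length(nodes) <= 2) {
    out <- component
    out@isTree <- TRUE
    return(out)
  }
  a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
  e <- data.frame(from = a, to = b, weight = e$weight, stringsAsFactors = FALSE)
  e <- e[order(-e$weight, e$from, e$to), , drop = FALSE]
  parent <- stats::setNames(seq_along(nodes), nodes)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(e))
  for (k in seq_len(nrow(e))) {
    ra <- findRoot(match(e$from[k], nodes))
    rb <- findRoot(match(e$to[k], nodes))
    if (ra != rb) {
      keep[k] <- TRUE
      parent[ra] <- rb
    }
  }
  tree <- e[keep, , drop = FALSE]
  tree <- tree[order(tree$from, tree$to), , drop = FALSE]
  rownames(tree) <- NULL
  new("ProvenanceGraph", nodes = nodes, edges = tree,
      nodeMeta = component@nodeMeta, isTree = TRUE, level = component@level)
}

#' Image-level provenance graphs of a corpus table
#'
#' Convenience wrapper: connected components at the threshold, then the
#' maximum spanning tree of each.
#'
#' @inheritParams provenanceComponents
#' @return list(components = ..., trees = ...).
#' @export
provenanceGraphs <- function(table, threshold = 0.01, nodeMeta = NULL) {
  comps <- provenanceComponents(table, threshold, nodeMeta)
  list(components = comps, trees = lapply(comps, maximumSpanningTree))
}

#' Serialize / read a content-shared table as CSV
#'
#' Columns: row_id, col_id, score (one row per directional cell).
#'
#' @param table a \linkS4class{ContentSharedTable}.
#' @param path CSV file path.
#' @return `writeSharedTable` the path invisibly; `readSharedTable` the
#'   table (its processed registry restored from the recorded pairs).
#' @export
writeSharedTable <- function(table, path) {
  utils::write.csv(table@entries, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeSharedTable
#' @export
readSharedTable <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c("character", "character", "numeric"))
  t <- contentSharedTable()
  t@entries <- e
  t@processed <- sort(unique(pairKey(e$row_id, e$col_id)))
  t
}
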