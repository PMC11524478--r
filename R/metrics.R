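# Evaluation against ground-truth annotations: content pairing (links),
# content grouping (components vs annotated categories), and content
# classification (suspicious vs not), each summarized by a harmonic mean.

harmonicMean <- function(a, b) if (a + b == 0) 0 else 2 * a * b / (a + b)

canonicalLinks <- function(links) {
  if (is.null(links) || length(links) == 0) return(character(0))
  if (is.data.frame(links)) links <- as.matrix(links[, 1:2])
  if (is.matrix(links)) {
    if (nrow(links) == 0) return(character(0))
    unique(paste(pmin(links[, 1], links[, 2]),
                 pmax(links[, 1], links[, 2]), sep = "||"))
  } else unique(links)
}

#' Content pairing: link precision, recall and their harmonic mean
#'
#' Link precision LP is the fraction of predicted links that are annotated;
#' link recall LR is the fraction of annotated links that were predicted;
#' CP is their harmonic mean (defined as 0 when both are 0, and all three as
#' 1.0 when both the prediction and the annotation are empty).
#'
#' @param predicted links as a 2-column matrix/data.frame of unordered id
#'   pairs (e.g. [tableLinks()] output).
#' @param truth annotated links in the same form, or a GroundTruth list from
#'   [readGroundTruth()] (uses its links at `level`).
#' @param level "image" or "document" when `truth` is a GroundTruth.
#' @param corpusIds optional character vector of all valid ids; links over
#'   unknown ids raise a validation error.
#' @return named numeric c(LP, LR, CP).
#' @export
contentPairing <- function(predicted, truth, level = "image",
                           corpusIds = NULL) {
  if (inherits(truth, "GroundTruth"))
    truth <- if (level == "image") truth$imageLinks else truth$docLinks
  p <- canonicalLinks(predicted)
  t <- canonicalLinks(truth)
  if (!is.null(corpusIds)) {
    ids <- unique(unlist(strsplit(c(p, t), "||", fixed = TRUE)))
    if (!all(ids %in% corpusIds))
      stop("links reference ids absent from the corpus: ",
           paste(setdiff(ids, corpusIds), collapse = ", "))
  }
  correct <- length(intersect(p, t))
  LP <- if (length(p) == 0) as.numeric(length(t) == 0) else correct / length(p)
  LR <- if (length(t) == 0) as.numeric(length(p) == 0) else correct / length(t)
  c(LP = LP, LR = LR, CP = harmonicMean(LP, LR))
}

#' Content grouping: node precision, recall and their harmonic mean
#'
#' Each predicted group (a connected component) is matched to the annotated
#' category with which it shares the most members (greedy, largest overlap
#' first, each category used at most once). For a matched pair, the group's
#' node precision is overlap / |predicted group| and the category's node
#' recall is overlap / |annotated category|; unmatched groups and categories
#' contribute zeros. NP and NR are the averages over predicted groups and
#' annotated categories respectively; CG is their harmonic mean.
#'
#' @param predicted list of character vectors (disjoint predicted groups),
#'   or a list of \linkS4class{ProvenanceGraph} (their node sets are used).
#' @param truth named list of character vectors (category -> members), or a
#'   GroundTruth list.
#' @param level "image" or "document" when `truth` is a GroundTruth.
#' @return named numeric c(NP, NR, CG) with per-group values in
#'   attr(, "perGroup").
#' @export
contentGrouping <- function(predicted, truth, level = "image") {
  if (inherits(truth, "GroundTruth"))
    truth <- if (level == "image") truth$imageGroups else truth$docGroups
  if (length(predicted) > 0 && is(predicted[[1]], "ProvenanceGraph"))
    predicted <- lapply(predicted, graphNodes)
  allPred <- unlist(predicted)
  if (anyDuplicated(allPred))
    stop("predicted groups must be disjoint")
  nP <- length(predicted); nT <- length(truth)
  if (nP == 0 && nT == 0)
    return(structure(c(NP = 1, NR = 1, CG = 1), perGroup = NULL))
  ov <- matrix(0L, nrow = max(nP, 1), ncol = max(nT, 1))
  for (i in seq_len(nP)) for (j in seq_len(nT))
    ov[i, j] <- length(intersect(predicted[[i]], truth[[j]]))
  npVals <- numeric(nP); nrVals <- numeric(max(nT, 0))
  usedP <- logical(nP); usedT <- logical(nT)
  repeat {
    ov2 <- ov
    if (nP > 0) ov2[usedP, ] <- -1L
    if (nT > 0) ov2[, usedT] <- -1L
    best <- max(ov2)
    if (best <= 0 || nP == 0 || nT == 0) break
    hit <- which(ov2 == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    i <- hit[1]; j <- hit[2]
    npVals[i] <- best / length(predicted[[i]])
    nrVals[j] <- best / length(truth[[j]])
    usedP[i] <- TRUE; usedT[j] <- TRUE
  }
  NP <- if (nP == 0) 0 else mean(npVals)
  NR <- if (nT == 0) 0 else mean(nrVals)
  structure(c(NP = NP, NR = NR, CG = harmonicMean(NP, NR)),
            perGroup = list(NP = npVals, NR = nrVals))
}

#' Content classification: suspicious-item precision, recall and harmonic mean
#'
#' The predicted suspicious set is every id appearing in any provenance
#' graph; precision and recall are computed against the annotated suspicious
#' set, and CC is their harmonic mean.
#'
#' @param predicted character vector of predicted suspicious ids, or a list
#'   of \linkS4class{ProvenanceGraph}.
#' @param truth character vector of annotated suspicious ids, or a
#'   GroundTruth list.
#' @param level "image" or "document" when `truth` is a GroundTruth.
#' @return named numeric c(precision, recall, CC).
#' @export
contentClassification <- function(predicted, truth, level = "image") {
  if (inherits(truth, "GroundTruth"))
    truth <- if (level == "image") truth$suspiciousPanels
             else truth$suspiciousDocs
  if (is.list(predicted) && length(predicted) > 0 &&
      is(predicted[[1]], "ProvenanceGraph"))
    predicted <- unlist(lapply(predicted, graphNodes))
  p <- unique(predicted); t <- unique(truth)
  tp <- length(intersect(p, t))
  precision <- if (length(p) == 0) as.numeric(length(t) == 0) else tp / length(p)
  recall <- if (length(t) == 0) as.numeric(length(p) == 0) else tp / length(t)
  c(precision = precision, recall = recall,
    CC = harmonicMean(precision, recall))
}

#' Read ground-truth annotations
#'
#' Parses a corpus annotation JSON (the schema written by
#' [generateCorpus()]): per-document figure/panel records with optional group
#' labels. Panel ids follow the deterministic reading-order assignment of
#' [cropAndFilter()]. Derived fields: the image-level link set (all
#' within-group cross-document pairs), image-level groups, document-level
#' links (document pairs sharing a group), document-level groups (connected
#' components of the document links), and both suspicious sets.
#'
#' @param path annotation JSON file (e.g. `truth.json`).
#' @return a list with class "GroundTruth".
#' @export
readGroundTruth <- function(path) {
  ann <- readAnnotations(path)
  groups <- list()
  if (!is.null(ann$groups)) {
    for (g in ann$groups)
      groups[[g$label]] <- sort(unlist(g$members))
  } else {
    # reconstruct group membership from per-panel labels
    for (doc in ann$documents)
      for (fg in doc$figures)
        for (i in seq_along(fg$panels)) {
          p <- fg$panels[[i]]
          if (!is.null(p$group))
            groups[[p$group]] <- c(groups[[p$group]],
                                   sprintf("%s/p%d", fg$figure_id, i))
        }
    groups <- lapply(groups, sort)
  }
  docOf <- function(id) sub("/.*$", "", id)
  imageLinks <- character(0)
  for (g in groups) {
    if (length(g) < 2) next
    cmb <- utils::combn(g, 2)
    cross <- docOf(cmb[1, ]) != docOf(cmb[2, ])
    imageLinks <- c(imageLinks,
                    paste(pmin(cmb[1, cross], cmb[2, cross]),
                          pmax(cmb[1, cross], cmb[2, cross]), sep = "||"))
  }
  imageLinks <- sort(unique(imageLinks))
  docLinks <- character(0)
  for (g in groups) {
    d <- sort(unique(docOf(g)))
    if (length(d) >= 2) {
      cmb <- utils::combn(d, 2)
      docLinks <- c(docLinks, paste(cmb[1, ], cmb[2, ], sep = "||"))
    }
  }
  docLinks <- sort(unique(docLinks))
  docGroups <- list()
  if (length(docLinks) > 0) {
    parts <- strsplit(docLinks, "||", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, character(1), 1),
                        to = vapply(parts, `[`, character(1), 2),
                        weight = 1, stringsAsFactors = FALSE)
    comps <- componentsFromEdges(edges, level = "document")
    docGroups <- stats::setNames(lapply(comps, graphNodes),
                                 paste0("DG", seq_along(comps)))
  }
  suspiciousPanels <- sort(unique(unlist(groups)))
  out <- list(imageGroups = groups,
              imageLinks = imageLinks,
              docGroups = docGroups,
              docLinks = docLinks,
              suspiciousPanels = suspiciousPanels,
              suspiciousDocs = sort(unique(docOf(suspiciousPanels))))
  class(out) <- "GroundTruth"
  out
}

#' Score a corpus analysis against ground truth
#'
#' Computes the three task metrics at one level. At the image level the
#' predictions are derived from the content-shared table (links = suspicious
#' pairs, groups = connected components, suspicious set = panels in any
#' graph); at the document level from the document matrix.
#'
#' @param result a \linkS4class{ContentSharedTable} (image level) or
#'   \linkS4class{DocumentMatrix} (document level).
#' @param truth a GroundTruth from [readGroundTruth()].
#' @param level "image" or "document".
#' @param threshold score threshold for the image level (default 0.01).
#' @return a \linkS4class{MetricsReport}.
#' @export
evaluateProvenance <- function(result, truth, level = c("image", "document"),
                               threshold = 0.01) {
  level <- match.arg(level)
  if (level == "image") {
    stopifnot(is(result, "ContentSharedTable"))
    links <- tableLinks(result, threshold)
    comps <- provenanceComponents(result, threshold)
  } else {
    stopifnot(is(result, "DocumentMatrix"))
    dg <- documentGraphs(result)
    comps <- dg$components
    m <- result@counts
    idx <- which(upper.tri(m) & m >= 1, arr.ind = TRUE)
    links <- data.frame(from = rownames(m)[idx[, 1]],
                        to = colnames(m)[idx[, 2]], stringsAsFactors = FALSE)
  }
  cp <- contentPairing(links, truth, level)
  cg <- contentGrouping(comps, truth, level)
  cc <- contentClassification(comps, truth, level)
  new("MetricsReport", level = level,
      values = c(cp, NP = unname(cg["NP"]), NR = unname(cg["NR"]),
                 CG = unname(cg["CG"]), cc))
}

#' Write a metrics report as JSON
#'
#' @param report a \linkS4class{MetricsReport}.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  writeLines(jsonlite::toJSON(list(level = report@level,
                                   metrics = as.list(report@values)),
                              auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}
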