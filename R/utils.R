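# internal helpers shared across modules

# run expr with a temporarily fixed RNG state, restoring the caller's state
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

# canonical unordered pair key
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "||")
}

# deterministic 32-bit string hash (FNV-1a), used to derive per-pair seeds
stringHash <- function(s) {
  v <- utf8ToInt(s)
  h <- 2166136261
  for (x in v) {
    h <- bitwXor(as.integer(h %% 2^31), x)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h)
}

# ITU-R BT.601 luma from an h x w x 3 array
toGray <- function(raster) {
  0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3]
}

# clamp to [0, 1]
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# promote grayscale matrix or h x w x 1 to h x w x 3
asRGB <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3), dim = c(dim(x), 3L))
  if (length(dim(x)) == 3L && dim(x)[3] == 1L)
    x <- array(rep(x[, , 1], 3), dim = c(dim(x)[1:2], 3L))
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  x
}

# horizontal / vertical flip of an h x w x 3 array
flipRaster <- function(raster, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") raster[, rev(seq_len(dim(raster)[2])), , drop = FALSE]
  else raster[rev(seq_len(dim(raster)[1])), , , drop = FALSE]
}

panelWidth <- function(panel) dim(panel@raster)[2]
panelHeight <- function(panel) dim(panel@raster)[1]

#' Accessors for panel objects
#'
#' @param panel a \linkS4class{Panel}.
#' @return `panelId` the panel id, `panelType` its type, `panelRaster` the
#'   h x w x 3 raster array, `panelDoc` the owning document id.
#' @export
panelId <- function(panel) panel@panelId

#' @rdname panelId
#' @export
panelType <- function(panel) panel@panelType

#' @rdname panelId
#' @export
panelRaster <- function(panel) panel@raster

#' @rdname panelId
#' @export
panelDoc <- function(panel) panel@docId

#' Accessors for provenance graphs
#'
#' @param graph a \linkS4class{ProvenanceGraph}.
#' @return `graphNodes` the node ids; `graphEdges` a data.frame(from, to,
#'   weight); `nodeDegrees` a named integer vector (the highest-degree node of
#'   a spanning tree is the suspected hub of a reuse group).
#' @export
graphNodes <- function(graph) graph@nodes

#' @rdname graphNodes
#' @export
graphEdges <- function(graph) graph@edges

#' @rdname graphNodes
#' @export
nodeDegrees <- function(graph) {
  deg <- stats::setNames(integer(length(graph@nodes)), graph@nodes)
  if (nrow(graph@edges) > 0) {
    t1 <- table(graph@edges$from)
    t2 <- table(graph@edges$to)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

#' Accessor for the document count matrix
#'
#' @param x a \linkS4class{DocumentMatrix}.
#' @return the symmetric integer matrix of shared-element counts.
#' @export
documentCounts <- function(x) x@counts

#' Accessor for metric values
#'
#' @param x a \linkS4class{MetricsReport}.
#' @return named numeric vector (LP, LR, CP, NP, NR, CG, precision, recall, CC).
#' @export
metricValues <- function(x) x@values
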