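# shared test fixtures, all generated in code

newPanel <- function(raster, id = "d1/fig1/p1", type = "microscopy") {
  d <- dim(raster)
  new("Panel", panelId = id, docId = sub("/.*$", "", id),
      figureId = sub("/p[0-9]+$", "", id), bbox = c(0, 0, d[2], d[1]),
      panelType = type, raster = raster)
}

seededPanel <- function(seed, type = "microscopy", w = 180, h = 140,
                        id = "d1/fig1/p1") {
  r <- withr::with_seed(seed, synthPanel(type, width = w, height = h))
  newPanel(r, id = id, type = type)
}

# small corpus shared across test files (generated once per test run)
smallCorpusDir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "panelprov-small-corpus")
      if (!file.exists(file.path(dir, "truth.json"))) {
        spec <- fixtureSpec(seed = 42L, nDocuments = 10L, nMillDocuments = 3L,
                            figuresPerDocument = 1L, panelsPerFigure = 4L,
                            reuseGroups = list(list(label = "G1", size = 3L,
                                                    type = "microscopy")))
        generateCorpus(spec, dir)
      }
    }
    dir
  }
})

# independent convex hull + area oracle: gift wrapping and fan triangulation
# (deliberately not the shoelace formula used by the implementation)
oracleHullArea <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1]
    for (k in cand[-1]) {
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
        (pts[nxt, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      d1 <- sum((pts[k, ] - pts[cur, ])^2)
      d2 <- sum((pts[nxt, ] - pts[cur, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d1 > d2)) nxt <- k
    }
    if (nxt == start) break
    hull <- c(hull, nxt)
    if (length(hull) > n) break
  }
  if (length(hull) < 3) return(0)
  a <- 0
  p0 <- pts[hull[1], ]
  for (k in 2:(length(hull) - 1)) {
    p1 <- pts[hull[k], ]; p2 <- pts[hull[k + 1], ]
    a <- a + abs((p1[1] - p0[1]) * (p2[2] - p0[2]) -
                   (p2[1] - p0[1]) * (p1[2] - p0[2])) / 2
  }
  a
}

# breadth-first-search connected-components oracle over an edge list
oracleComponents <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], edges$from[i])
  }
  seen <- character(0)
  comps <- list()
  for (s in nodes) {
    if (s %in% seen) next
    queue <- s; members <- character(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% members) next
      members <- c(members, v)
      queue <- c(queue, setdiff(adj[[v]], members))
    }
    seen <- c(seen, members)
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# exhaustive spanning-tree enumeration oracle: maximum spanning-tree weight
oracleMaxSpanningWeight <- function(nodes, edges) {
  n <- length(nodes)
  m <- nrow(edges)
  if (n <= 1) return(0)
  best <- -Inf
  for (sel in utils::combn(seq_len(m), n - 1, simplify = FALSE)) {
    sub <- edges[sel, , drop = FALSE]
    comps <- oracleComponents(nodes, sub)
    if (length(comps) == 1) best <- max(best, sum(sub$weight))
  }
  best
}
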