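# panels used by the queue-loop tests: A and C are crops of B planted in
# three different documents, so similarity chains A -> B -> C
chainPanels <- function() {
  set.seed(41)
  S <- synthPanel("microscopy", 260, 200)
  list(A = newPanel(S[, 1:170, , drop = FALSE], id = "docA/fig1/p1"),
       B = newPanel(S, id = "docB/fig1/p1"),
       C = newPanel(S[, 90:260, , drop = FALSE], id = "docC/fig1/p1"))
}

# descriptor database with engineered cosine rankings: the probe's top-1 is
# B, and C ranks first only for queries from B (cos(A,B) = 0.707,
# cos(B,C) = 0.836, cos(A,C) = 0.204)
chainDB <- function(panels) {
  vecs <- rbind(c(1, 0, 0),
                c(1, 1, 0) / sqrt(2),
                c(0.2, 0.96, 0) / sqrt(0.2^2 + 0.96^2))
  rownames(vecs) <- names(panels)
  new("EvidenceDB", vectors = vecs,
      meta = data.frame(panel_id = names(panels),
                        doc_id = sub("/.*$", "", names(panels)),
                        panel_type = "microscopy", stringsAsFactors = FALSE),
      backend = "constructed")
}

test_that("the processing queue reaches second-tier neighbours by expansion", {
  ps <- chainPanels()
  panels <- stats::setNames(ps, vapply(ps, panelId, character(1)))
  db <- chainDB(panels)
  # K = 1: C is outside the probe's initial retrieval; it can only be
  # reached through the expansion with B's top-L neighbours
  cfg <- retrievalConfig(K = 1, L = 1)
  expect_identical(retrieveSimilar("docA/fig1/p1", db, k = 1)$panel_id,
                   "docB/fig1/p1")
  expect_identical(retrieveSimilar("docB/fig1/p1", db, k = 1)$panel_id,
                   "docC/fig1/p1")
  tab <- processProbe("docA/fig1/p1", panels, db, cfg = cfg)
  expect_true(panelprov:::pairKey("docA/fig1/p1", "docC/fig1/p1") %in%
                tab@processed)
})

test_that("the expansion threshold is inclusive", {
  ps <- chainPanels()
  panels <- stats::setNames(ps, vapply(ps, panelId, character(1)))
  db <- chainDB(panels)
  m <- matchAndVerify(ps$A, ps$B)
  sc <- contentSharingScore(m, ps$A, ps$B)
  mx <- max(sc)
  keyAC <- panelprov:::pairKey("docA/fig1/p1", "docC/fig1/p1")
  # threshold exactly at the observed score: pair recorded AND expanded
  tab <- processProbe("docA/fig1/p1", panels, db,
                      cfg = retrievalConfig(K = 1, L = 1, scoreThreshold = mx))
  expect_false(is.na(tableScore(tab, "docA/fig1/p1", "docB/fig1/p1")))
  expect_true(keyAC %in% tab@processed)
  # threshold just above: recorded in the table but not expanded
  tab <- processProbe("docA/fig1/p1", panels, db,
                      cfg = retrievalConfig(K = 1, L = 1,
                                            scoreThreshold = mx + 1e-9))
  expect_false(is.na(tableScore(tab, "docA/fig1/p1", "docB/fig1/p1")))
  expect_false(keyAC %in% tab@processed)
})

test_that("both directional cells of a pair are written together", {
  ps <- chainPanels()
  panels <- stats::setNames(ps, vapply(ps, panelId, character(1)))
  db <- buildEvidenceDB(panels)
  tab <- buildSharedTable(panels, db)
  e <- tab@entries
  expect_gt(nrow(e), 0)
  for (i in seq_len(nrow(e)))
    expect_false(is.na(tableScore(tab, e$col_id[i], e$row_id[i])))
  # no diagonal, no same-document cells
  expect_false(any(e$row_id == e$col_id))
  doc <- function(id) sub("/.*$", "", id)
  expect_false(any(doc(e$row_id) == doc(e$col_id)))
})

test_that("the full table recovers exactly the planted reuse group", {
  dir <- smallCorpusDir()
  panels <- ingestCorpus(figureDir = file.path(dir, "figures"),
                         annotations = file.path(dir, "truth.json"))
  db <- buildEvidenceDB(panels)
  tab <- buildSharedTable(panels, db)
  truth <- readGroundTruth(file.path(dir, "truth.json"))
  links <- tableLinks(tab, 0.01)
  predicted <- sort(paste(links$from, links$to, sep = "||"))
  expect_identical(predicted, truth$imageLinks)
  # every planted pair has both cells populated at or above threshold
  expect_equal(nrow(tab@entries), 2 * length(truth$imageLinks))
  expect_true(all(tab@entries$score >= 0.01))
  # a probe pair is never examined twice (registry is global)
  expect_false(anyDuplicated(tab@processed) > 0)
})

test_that("repeated runs produce identical tables", {
  dir <- smallCorpusDir()
  panels <- ingestCorpus(figureDir = file.path(dir, "figures"),
                         annotations = file.path(dir, "truth.json"))
  db <- buildEvidenceDB(panels)
  t1 <- buildSharedTable(panels, db)
  t2 <- buildSharedTable(panels, db)
  expect_identical(t1@entries, t2@entries)
  expect_identical(t1@processed, t2@processed)
})

test_that("connected components match a breadth-first-search oracle", {
  # forced small example
  edges <- data.frame(from = c("A", "B", "D"), to = c("B", "C", "E"),
                      weight = c(0.5, 0.4, 0.9), stringsAsFactors = FALSE)
  comps <- provenanceComponents(edges)
  expect_length(comps, 2)
  expect_identical(graphNodes(comps[[1]]), c("A", "B", "C"))
  expect_identical(graphNodes(comps[[2]]), c("D", "E"))
  # random tables vs oracle
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(5:30, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    m <- sample(0:(2 * n), 1)
    if (m == 0) next
    edges <- unique(data.frame(
      from = sample(nodes, m, replace = TRUE),
      to = sample(nodes, m, replace = TRUE),
      weight = runif(m, 0.011, 1), stringsAsFactors = FALSE))
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    if (nrow(edges) == 0) next
    sw <- edges$from > edges$to
    tmp <- edges$from[sw]; edges$from[sw] <- edges$to[sw]; edges$to[sw] <- tmp
    edges <- edges[!duplicated(edges[, 1:2]), ]
    comps <- provenanceComponents(edges)
    got <- lapply(comps, graphNodes)
    touched <- sort(unique(c(edges$from, edges$to)))
    want <- oracleComponents(touched, edges)
    want <- want[order(-lengths(want),
                       vapply(want, `[`, character(1), 1))]
    expect_identical(got, want)
  }
})

test_that("empty tables yield no components", {
  expect_length(provenanceComponents(contentSharedTable()), 0)
})

test_that("maximum spanning trees maximize weight with deterministic ties", {
  # a triangle drops its minimum edge
  tri <- new("ProvenanceGraph", nodes = c("A", "B", "C"),
             edges = data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                                weight = c(0.9, 0.8, 0.5),
                                stringsAsFactors = FALSE),
             isTree = FALSE, level = "image")
  mst <- maximumSpanningTree(tri)
  expect_true(mst@isTree)
  expect_equal(nrow(mst@edges), 2)
  expect_equal(sum(mst@edges$weight), 1.7)
  # an input that is already a tree is returned unchanged
  tree <- new("ProvenanceGraph", nodes = c("A", "B", "C"),
              edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                                 weight = c(0.2, 0.3), stringsAsFactors = FALSE),
              isTree = FALSE, level = "image")
  mst <- maximumSpanningTree(tree)
  expect_equal(mst@edges[, c("from", "to")], tree@edges[, c("from", "to")])
  # equal weights: the lexicographically smaller edge pair wins
  sq <- new("ProvenanceGraph", nodes = c("A", "B", "C", "D"),
            edges = data.frame(from = c("A", "B", "C", "A"),
                               to = c("B", "C", "D", "D"),
                               weight = 0.5, stringsAsFactors = FALSE),
            isTree = FALSE, level = "image")
  mst <- maximumSpanningTree(sq)
  expect_identical(paste(mst@edges$from, mst@edges$to),
                   c("A B", "A D", "B C"))
  # hub surfacing: degrees are reported per node
  deg <- nodeDegrees(mst)
  expect_equal(sum(deg), 2 * nrow(mst@edges))
})

test_that("every panel appears in exactly one provenance graph", {
  set.seed(43)
  edges <- data.frame(from = c("a", "b", "c", "e"), to = c("b", "c", "d", "f"),
                      weight = runif(4, 0.1, 1), stringsAsFactors = FALSE)
  comps <- provenanceComponents(edges)
  all_nodes <- unlist(lapply(comps, graphNodes))
  expect_false(anyDuplicated(all_nodes) > 0)
  expect_setequal(all_nodes, c("a", "b", "c", "d", "e", "f"))
})

test_that("content-shared tables round-trip through CSV", {
  dir <- smallCorpusDir()
  panels <- ingestCorpus(figureDir = file.path(dir, "figures"),
                         annotations = file.path(dir, "truth.json"))
  db <- buildEvidenceDB(panels)
  tab <- buildSharedTable(panels, db)
  path <- file.path(tempdir(), "table.csv")
  writeSharedTable(tab, path)
  tab2 <- readSharedTable(path)
  expect_equal(tab@entries, tab2@entries)
})
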