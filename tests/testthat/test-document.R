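toyTable <- function(entries) {
  t <- contentSharedTable()
  t@entries <- entries
  t@processed <- sort(unique(panelprov:::pairKey(entries$row_id,
                                                 entries$col_id)))
  t
}

toyMeta <- function(ids) {
  data.frame(panel_id = ids, doc_id = sub("/.*$", "", ids),
             stringsAsFactors = FALSE)
}

test_that("an empty table gives an all-zero matrix", {
  ids <- c("d1/f/p1", "d2/f/p1", "d3/f/p1")
  M <- buildDocumentMatrix(contentSharedTable(), toyMeta(ids))
  expect_true(all(documentCounts(M) == 0))
  expect_identical(rownames(documentCounts(M)), c("d1", "d2", "d3"))
  expect_length(documentGraphs(M)$components, 0)
})

test_that("documents sharing k suspicious panel pairs get d_ij = k", {
  e <- data.frame(
    row_id = c("d1/f/p1", "d2/f/p1", "d1/f/p2", "d2/f/p2", "d1/f/p3", "d2/f/p3"),
    col_id = c("d2/f/p1", "d1/f/p1", "d2/f/p2", "d1/f/p2", "d2/f/p3", "d1/f/p3"),
    score = c(0.5, 0.4, 0.9, 0.2, 0.03, 0.011), stringsAsFactors = FALSE)
  ids <- unique(c(e$row_id, e$col_id, "d3/f/p1"))
  M <- buildDocumentMatrix(toyTable(e), toyMeta(ids))
  m <- documentCounts(M)
  expect_equal(m["d1", "d2"], 3)
  expect_equal(m["d2", "d1"], 3)
  expect_equal(sum(m), 6)          # symmetric, nothing else
  expect_equal(diag(m), c(d1 = 0, d2 = 0, d3 = 0))
})

test_that("document counts match an independent pair-counting oracle", {
  set.seed(51)
  for (rep in 1:20) {
    nDocs <- sample(3:8, 1)
    ids <- sprintf("d%d/f/p%d", rep(seq_len(nDocs), each = 4), 1:4)
    npairs <- sample(1:15, 1)
    a <- sample(ids, npairs, replace = TRUE)
    b <- sample(ids, npairs, replace = TRUE)
    keep <- sub("/.*$", "", a) != sub("/.*$", "", b)
    a <- a[keep]; b <- b[keep]
    if (length(a) == 0) next
    key <- panelprov:::pairKey(a, b)
    dup <- duplicated(key)
    a <- a[!dup]; b <- b[!dup]
    sc <- runif(length(a), 0.011, 1)
    e <- data.frame(row_id = c(a, b), col_id = c(b, a), score = c(sc, sc / 2),
                    stringsAsFactors = FALSE)
    M <- buildDocumentMatrix(toyTable(e), toyMeta(ids), threshold = 0.01)
    # oracle: iterate unordered suspicious pairs and count per doc pair
    want <- matrix(0L, nDocs, nDocs,
                   dimnames = list(sort(unique(sub("/.*$", "", ids))),
                                   sort(unique(sub("/.*$", "", ids)))))
    for (k in seq_along(a)) {
      di <- sub("/.*$", "", a[k]); dj <- sub("/.*$", "", b[k])
      want[di, dj] <- want[di, dj] + 1L
      want[dj, di] <- want[dj, di] + 1L
    }
    expect_identical(documentCounts(M), want)
    # sum of all cells / 2 = number of suspicious cross-document pairs
    expect_equal(sum(documentCounts(M)) / 2, length(a))
  }
})

test_that("panels without a known document are a data-integrity error", {
  e <- data.frame(row_id = c("dX/f/p1", "d1/f/p1"),
                  col_id = c("d1/f/p1", "dX/f/p1"),
                  score = c(0.5, 0.5), stringsAsFactors = FALSE)
  expect_error(buildDocumentMatrix(toyTable(e), toyMeta("d1/f/p1")),
               "unknown")
})

test_that("document graphs contain exactly the documents with shared panels", {
  dir <- smallCorpusDir()
  panels <- ingestCorpus(figureDir = file.path(dir, "figures"),
                         annotations = file.path(dir, "truth.json"))
  db <- buildEvidenceDB(panels)
  tab <- buildSharedTable(panels, db)
  M <- buildDocumentMatrix(tab, db@meta)
  truth <- readGroundTruth(file.path(dir, "truth.json"))
  dg <- documentGraphs(M)
  expect_length(dg$components, 1)
  expect_identical(graphNodes(dg$components[[1]]), truth$suspiciousDocs)
  # distractor documents appear in no graph
  clean <- setdiff(sort(unique(db@meta$doc_id)), truth$suspiciousDocs)
  expect_false(any(clean %in% unlist(lapply(dg$components, graphNodes))))
  # trees are spanning and acyclic
  tr <- dg$trees[[1]]
  expect_true(tr@isTree)
  expect_equal(nrow(tr@edges), length(tr@nodes) - 1)
})

test_that("binarized document components equal the BFS oracle", {
  set.seed(52)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    docs <- sprintf("d%02d", seq_len(n))
    m <- matrix(0L, n, n, dimnames = list(docs, docs))
    npair <- sample(0:6, 1)
    for (k in seq_len(npair)) {
      ij <- sample(n, 2)
      m[ij[1], ij[2]] <- m[ij[1], ij[2]] + 1L
      m[ij[2], ij[1]] <- m[ij[2], ij[1]] + 1L
    }
    M <- new("DocumentMatrix", counts = m)
    comps <- lapply(documentGraphs(M)$components, graphNodes)
    idx <- which(upper.tri(m) & m >= 1, arr.ind = TRUE)
    edges <- data.frame(from = docs[idx[, 1]], to = docs[idx[, 2]],
                        stringsAsFactors = FALSE)
    touched <- sort(unique(c(edges$from, edges$to)))
    want <- oracleComponents(touched, edges)
    want <- want[order(-lengths(want), vapply(want, `[`, character(1), 1))]
    expect_identical(comps, want)
  }
})
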