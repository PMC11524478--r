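test_that("panel synthesis is deterministic given the RNG state", {
  a <- withr::with_seed(71, synthPanel("microscopy"))
  b <- withr::with_seed(71, synthPanel("microscopy"))
  expect_identical(a, b)
})

test_that("panel types have their intended keypoint structure", {
  set.seed(72)
  micro <- synthPanel("microscopy", 180, 140)
  blot <- synthPanel("blots", 180, 140)
  nMicro <- nrow(extractKeypoints(micro)$coordinates)
  nBlot <- nrow(extractKeypoints(blot)$coordinates)
  expect_gte(nMicro, 20)
  expect_lt(nBlot, nMicro)  # blots are deliberately low-entropy
  flow <- synthPanel("flow_cytometry", 180, 140)
  whiteFrac <- mean(apply(flow, c(1, 2), min) > 0.95)
  expect_gte(whiteFrac, 0.6)
})

test_that("transformation ops apply their recorded parameters exactly", {
  set.seed(73)
  r <- synthPanel("microscopy", 120, 100)
  cr <- applyTransform(r, list(kind = "crop", x0 = 10, y0 = 5, w = 60, h = 50))
  expect_identical(cr, r[6:55, 11:70, , drop = FALSE])
  rs <- applyTransform(r, list(kind = "rescale", factor = 0.5))
  expect_equal(dim(rs)[1:2], c(50, 60))
  fl <- applyTransform(r, list(kind = "hflip"))
  expect_identical(fl[, 1, ], r[, 120, ])
  sp <- applyTransform(r, list(kind = "splice_onto_background",
                               bg = 0.9, pad = 8))
  expect_equal(dim(sp)[1:2], c(116, 136))
  expect_equal(sp[1, 1, ], rep(0.9, 3))
  expect_error(applyTransform(r, list(kind = "warp")), "unknown")
})

test_that("corpus generation is reproducible byte for byte", {
  spec <- fixtureSpec(seed = 99L, nDocuments = 4L, nMillDocuments = 2L,
                      figuresPerDocument = 1L, panelsPerFigure = 2L,
                      reuseGroups = list(list(label = "Z1", size = 2L,
                                              type = "microscopy")))
  d1 <- file.path(tempdir(), "repro1")
  d2 <- file.path(tempdir(), "repro2")
  unlink(c(d1, d2), recursive = TRUE)
  generateCorpus(spec, d1)
  generateCorpus(spec, d2)
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
  f <- list.files(file.path(d1, "figures"))
  expect_identical(f, list.files(file.path(d2, "figures")))
  for (fn in f)
    expect_identical(readBin(file.path(d1, "figures", fn), raw(), 1e7),
                     readBin(file.path(d2, "figures", fn), raw(), 1e7))
})

test_that("group structure and suspicious sets follow the fixture specification", {
  dir <- smallCorpusDir()
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth$groups, 1)
  expect_length(truth$groups[[1]]$members, 3)
  expect_length(truth$suspicious_documents, 3)
  # transformation parameters are recorded for every reuse instance
  expect_length(truth$transforms, 3)
  nOps <- vapply(truth$transforms, function(t) length(t$ops), integer(1))
  expect_equal(sum(nOps == 0), 1)  # one untransformed original per group
})

test_that("infeasible specs are rejected", {
  expect_error(fixtureSpec(nDocuments = 3, nMillDocuments = 1,
                           figuresPerDocument = 1, panelsPerFigure = 2,
                           reuseGroups = list(list(label = "G", size = 5,
                                                   type = "microscopy"))),
               "infeasible")
  expect_error(fixtureSpec(nDocuments = 3, nMillDocuments = 4), "exceed")
})

test_that("corpora can scale a reference suspect-to-distractor ratio", {
  # a 1/10-scale corpus of the reference collection: 12 mill among 472
  spec <- fixtureSpec(seed = 1L, nDocuments = 472L, nMillDocuments = 12L,
                      figuresPerDocument = 1L, panelsPerFigure = 2L,
                      reuseGroups = list(list(label = "G", size = 12L,
                                              type = "microscopy")))
  expect_equal(spec$nMillDocuments / spec$nDocuments, 12 / 472)
  expect_equal(spec$nMillDocuments, 12L)
})

test_that("affine copies carry an exact ground-truth homography", {
  set.seed(74)
  r <- synthPanel("microscopy", 100, 80)
  tr <- affineResample(r, scale = 2, theta = 0)
  expect_equal(dim(tr$raster)[1:2], c(160, 200))
  # the planted H maps source corners onto copy corners
  corners <- cbind(c(0, 99), c(0, 79))
  proj <- panelprov:::applyHomography(tr$H, corners)
  expect_equal(proj[, 1], c(0.5, 198.5), tolerance = 1e-9)
  # identity transform reproduces the raster
  id <- affineResample(r, 1, 0)
  expect_equal(id$raster, r, tolerance = 1e-9)
})
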