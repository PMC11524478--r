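test_that("fixture PDFs round-trip their embedded rasters", {
  set.seed(1)
  rasters <- lapply(1:3, function(i) synthPanel("microscopy", 120, 90))
  pdf <- file.path(tempdir(), "roundtrip.pdf")
  writeMiniPdf(rasters, pdf)
  figs <- extractFigures(pdf, minSize = 64)
  expect_length(figs, 3)
  expect_equal(vapply(figs, function(f) f@figureId, character(1)),
               sprintf("roundtrip/fig%d", 1:3))
  for (i in 1:3) {
    # stored at 8-bit depth: lossless up to quantization
    expect_lt(max(abs(figs[[i]]@raster - rasters[[i]])), 1 / 255)
  }
})

test_that("figure extraction applies the minimum-size filter", {
  set.seed(2)
  rasters <- list(synthPanel("microscopy", 120, 90),
                  synthPanel("microscopy", 30, 30))
  pdf <- file.path(tempdir(), "minsize.pdf")
  writeMiniPdf(rasters, pdf)
  expect_length(extractFigures(pdf, minSize = 64), 1)
  expect_length(extractFigures(pdf, minSize = 128), 0)  # empty, not an error
})

test_that("unreadable PDFs raise an ingest error naming the file", {
  bad <- file.path(tempdir(), "notapdf.pdf")
  writeLines("hello", bad)
  expect_error(extractFigures(bad), "notapdf")
})

test_that("directory mode reads figures in filename order", {
  d <- file.path(tempdir(), "figdir")
  dir.create(d, showWarnings = FALSE)
  set.seed(3)
  png::writePNG(synthPanel("microscopy", 100, 80), file.path(d, "b.png"))
  png::writePNG(synthPanel("blots", 110, 90), file.path(d, "a.png"))
  figs <- extractFigures(d, docId = "docX")
  expect_length(figs, 2)
  expect_equal(dim(figs[[1]]@raster)[1:2], c(90, 110))  # a.png first
  expect_equal(figs[[2]]@figureId, "docX/fig2")
})

test_that("heuristic splitter recovers a planted panel grid", {
  set.seed(4)
  gutter <- 12
  panels <- lapply(1:4, function(i) synthPanel("microscopy", 100, 80))
  fig <- array(1, dim = c(2 * 80 + 3 * gutter, 2 * 100 + 3 * gutter, 3))
  planted <- list()
  for (i in 1:4) {
    r <- (i - 1) %/% 2; cc <- (i - 1) %% 2
    x0 <- gutter + cc * (100 + gutter); y0 <- gutter + r * (80 + gutter)
    fig[(y0 + 1):(y0 + 80), (x0 + 1):(x0 + 100), ] <- panels[[i]]
    planted[[i]] <- c(x0, y0, x0 + 100, y0 + 80)
  }
  fi <- new("FigureImage", figureId = "d/fig1", docId = "d", raster = fig)
  boxes <- detectPanels(fi, backend = "heuristic")
  expect_equal(nrow(boxes), 4)
  ious <- vapply(seq_len(4), function(i) {
    best <- 0
    for (j in seq_len(nrow(boxes)))
      best <- max(best, panelprov:::iou(planted[[i]],
                                       as.numeric(boxes[j, 1:4])))
    best
  }, numeric(1))
  expect_gte(mean(ious), 0.8)
  expect_true(all(boxes$type == "unknown"))
})

test_that("heuristic splitter degenerates to one full-figure box", {
  set.seed(5)
  fi <- new("FigureImage", figureId = "d/fig1", docId = "d",
            raster = synthPanel("microscopy", 150, 120))
  boxes <- detectPanels(fi, backend = "heuristic")
  expect_equal(nrow(boxes), 1)
  expect_equal(as.numeric(boxes[1, 1:4]), c(0, 0, 150, 120))
})

test_that("annotation backend passes boxes through and deduplicates overlaps", {
  set.seed(6)
  fi <- new("FigureImage", figureId = "docA/fig1", docId = "docA",
            raster = array(0.5, dim = c(200, 300, 3)))
  ann <- list(documents = list(list(
    doc_id = "docA",
    figures = list(list(figure_id = "docA/fig1", file = "x.png",
                        panels = list(
                          list(bbox = c(0, 0, 100, 100), type = "microscopy"),
                          list(bbox = c(120, 0, 220, 100), type = "blots"),
                          list(bbox = c(0, 110, 100, 200), type = "flow_cytometry"),
                          list(bbox = c(120, 110, 290, 200), type = "graphs_plots")))))))
  boxes <- detectPanels(fi, backend = "annotation", annotations = ann)
  expect_equal(nrow(boxes), 4)
  expect_setequal(boxes$type,
                  c("microscopy", "blots", "flow_cytometry", "graphs_plots"))
  # duplicate box (IoU > 0.8) collapses onto the higher confidence
  ann$documents[[1]]$figures[[1]]$panels <-
    list(list(bbox = c(0, 0, 100, 100), type = "microscopy", confidence = 0.9),
         list(bbox = c(2, 2, 100, 100), type = "blots", confidence = 0.5))
  boxes <- detectPanels(fi, backend = "annotation", annotations = ann)
  expect_equal(nrow(boxes), 1)
  expect_equal(boxes$type, "microscopy")
  # boxes clipped to figure bounds
  ann$documents[[1]]$figures[[1]]$panels <-
    list(list(bbox = c(250, 150, 400, 300), type = "microscopy"))
  boxes <- detectPanels(fi, backend = "annotation", annotations = ann)
  expect_equal(as.numeric(boxes[1, 1:4]), c(250, 150, 300, 200))
})

test_that("model backend without a detector is a configuration error", {
  fi <- new("FigureImage", figureId = "d/fig1", docId = "d",
            raster = array(0.5, dim = c(100, 100, 3)))
  expect_error(detectPanels(fi, backend = "model"), "model")
  got <- detectPanels(fi, backend = "model", model = function(r)
    data.frame(x0 = 0, y0 = 0, x1 = 50, y1 = 50, type = "blots",
               confidence = 0.7))
  expect_equal(nrow(got), 1)
})

test_that("crop-and-filter drops excluded types and small panels, crops exactly", {
  set.seed(7)
  fig <- array(0.3, dim = c(300, 400, 3))
  fig[51:150, 41:180, 1] <- synthPanel("microscopy", 140, 100)[, , 1]
  fi <- new("FigureImage", figureId = "docB/fig2", docId = "docB", raster = fig)
  boxes <- data.frame(
    x0 = c(40, 200, 40, 200, 330),
    y0 = c(50, 50, 180, 180, 180),
    x1 = c(180, 320, 180, 320, 390),
    y1 = c(150, 150, 280, 280, 230),
    type = c("microscopy", "graphs_plots", "blots", "flow_cytometry",
             "body_imaging"),
    confidence = 1, stringsAsFactors = FALSE)
  panels <- cropAndFilter(fi, boxes)
  # graphs_plots dropped; 60x50 body_imaging below the 64 px minimum dropped
  expect_length(panels, 3)
  expect_false(any(vapply(panels, panelType, character(1)) == "graphs_plots"))
  # pixel-identical crop
  p1 <- panels[[1]]
  expect_identical(p1@raster, fig[51:150, 41:180, , drop = FALSE])
  # ids assigned in reading order over the full box set (gaps where dropped)
  expect_equal(vapply(panels, panelId, character(1)),
               c("docB/fig2/p1", "docB/fig2/p3", "docB/fig2/p4"))
  # unknown types retained when explicitly allowed
  boxes$type <- "unknown"
  panels <- cropAndFilter(fi, boxes, allowedTypes = "unknown", minSize = 32)
  expect_length(panels, 5)
})

test_that("panel id assignment is a pure function of figure and boxes", {
  set.seed(8)
  fi <- new("FigureImage", figureId = "d/fig1", docId = "d",
            raster = array(runif(200 * 300 * 3), dim = c(200, 300, 3)))
  boxes <- data.frame(x0 = c(150, 0), y0 = c(0, 10), x1 = c(300, 140),
                      y1 = c(90, 100), type = "microscopy", confidence = 1,
                      stringsAsFactors = FALSE)
  a <- cropAndFilter(fi, boxes)
  b <- cropAndFilter(fi, boxes[2:1, ])
  expect_identical(lapply(a, panelId), lapply(b, panelId))
  # left panel first despite being second in the input (reading order)
  expect_equal(a[[1]]@bbox[1], 0)
})
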