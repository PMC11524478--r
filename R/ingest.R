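#' Extract figure rasters from a source document
#'
#' A source document is either a PDF (embedded raster images are pulled from
#' the object stream, in deterministic object order) or a directory of raster
#' figures (PNG/JPEG/TIFF, read in filename order). Images smaller than
#' `minSize` in either dimension (icons, logos, label strips) are dropped.
#' Zero figures is a valid outcome, not an error; an unreadable or encrypted
#' PDF raises an ingest error naming the file.
#'
#' @param path a PDF file or a directory of raster images.
#' @param docId document identifier; defaults to the file/directory stem.
#' @param minSize minimum width and height in pixels (default 64).
#' @return list of \linkS4class{FigureImage} with ids "<doc_id>/fig<k>".
#' @export
extractFigures <- function(path, docId = NULL, minSize = 64L) {
  if (is.null(docId))
    docId <- sub("\\.[A-Za-z]+$", "", basename(path))
  rasters <-
    if (dir.exists(path)) {
      files <- sort(list.files(path, pattern = "\\.(png|jpe?g|tiff?)$",
                               ignore.case = TRUE, full.names = TRUE))
      out <- lapply(files, readRasterFile)
      Filter(function(r) min(dim(r)[1:2]) >= minSize, out)
    } else if (file.exists(path)) {
      pdfExtractImages(path, minSize = minSize)
    } else {
      stop("no such file or directory: ", path)
    }
  lapply(seq_along(rasters), function(k)
    new("FigureImage", figureId = sprintf("%s/fig%d", docId, k),
        docId = docId, raster = rasters[[k]]))
}

readRasterFile <- function(file) {
  ext <- tolower(tools::file_ext(file))
  r <- switch(ext,
    png = png::readPNG(file),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("jpeg package required to read ", file)
      jpeg::readJPEG(file)
    },
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("tiff package required to read ", file)
      tiff::readTIFF(file)
    },
    stop("unsupported figure format: ", file))
  asRGB(r)
}

iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) 0 else inter / union
}

emptyBoxes <- function() {
  data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
             y1 = numeric(0), type = character(0), confidence = numeric(0),
             stringsAsFactors = FALSE)
}

#' Locate panels within a compound figure
#'
#' Three detector backends: `annotation` passes through boxes supplied in the
#' annotation JSON (see [readAnnotations()]), `heuristic` splits the figure
#' recursively at whitespace gutters (panel type "unknown"), and `model`
#' calls an externally supplied detector function. Boxes are clipped to the
#' figure bounds and overlapping duplicates (IoU > 0.8) are collapsed keeping
#' the higher confidence.
#'
#' @param figure a \linkS4class{FigureImage}.
#' @param backend "annotation", "heuristic" or "model".
#' @param annotations parsed annotation list (annotation backend).
#' @param model a function(raster) returning a box data.frame (model backend);
#'   requesting the model backend without one is a configuration error.
#' @param minGutter minimum white-gutter width in pixels for the heuristic.
#' @return data.frame(x0, y0, x1, y1, type, confidence); coordinates 0-based,
#'   half-open on the max edges.
#' @export
detectPanels <- function(figure, backend = c("annotation", "heuristic", "model"),
                         annotations = NULL, model = NULL, minGutter = 10L) {
  backend <- match.arg(backend)
  h <- dim(figure@raster)[1]; w <- dim(figure@raster)[2]
  boxes <- switch(backend,
    annotation = {
      if (is.null(annotations))
        stop("annotation backend requires an annotations list")
      fig <- NULL
      for (doc in annotations$documents %||% annotations)
        for (fg in doc$figures)
          if (identical(fg$figure_id, figure@figureId)) fig <- fg
      if (is.null(fig)) emptyBoxes()
      else do.call(rbind, lapply(fig$panels, function(p)
        data.frame(x0 = p$bbox[1], y0 = p$bbox[2], x1 = p$bbox[3],
                   y1 = p$bbox[4], type = p$type %||% "unknown",
                   confidence = p$confidence %||% 1,
                   stringsAsFactors = FALSE)))
    },
    heuristic = {
      gray <- toGray(figure@raster)
      regions <- splitAtGutters(gray, 0L, 0L, minGutter)
      if (length(regions) == 0)
        data.frame(x0 = 0, y0 = 0, x1 = w, y1 = h, type = "unknown",
                   confidence = 0.5, stringsAsFactors = FALSE)
      else do.call(rbind, lapply(regions, function(b)
        data.frame(x0 = b[1], y0 = b[2], x1 = b[3], y1 = b[4],
                   type = "unknown", confidence = 0.5,
                   stringsAsFactors = FALSE)))
    },
    model = {
      if (!is.function(model))
        stop("model backend requested but no detector model configured")
      as.data.frame(model(figure@raster))
    })
  if (is.null(boxes) || nrow(boxes) == 0) return(emptyBoxes())
  # clip to figure bounds
  boxes$x0 <- pmax(0, pmin(boxes$x0, w)); boxes$x1 <- pmax(0, pmin(boxes$x1, w))
  boxes$y0 <- pmax(0, pmin(boxes$y0, h)); boxes$y1 <- pmax(0, pmin(boxes$y1, h))
  boxes <- boxes[boxes$x1 > boxes$x0 & boxes$y1 > boxes$y0, , drop = FALSE]
  # collapse duplicates, keeping the higher confidence
  boxes <- boxes[order(-boxes$confidence, boxes$x0, boxes$y0), , drop = FALSE]
  keep <- logical(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    bi <- as.numeric(boxes[i, 1:4])
    dup <- FALSE
    for (j in which(keep))
      if (iou(bi, as.numeric(boxes[j, 1:4])) > 0.8) { dup <- TRUE; break }
    keep[i] <- !dup
  }
  boxes <- boxes[keep, , drop = FALSE]
  rownames(boxes) <- NULL
  boxes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# recursive whitespace-gutter splitting; returns list of (x0, y0, x1, y1)
# boxes (0-based half-open) with white margins trimmed
splitAtGutters <- function(gray, offX, offY, minGutter, whiteLevel = 0.97) {
  h <- nrow(gray); w <- ncol(gray)
  rowWhite <- rowMeans(gray) >= whiteLevel
  colWhite <- colMeans(gray) >= whiteLevel
  if (all(rowWhite) || all(colWhite)) return(list())  # blank region
  gutterRuns <- function(white) {
    r <- rle(white)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values & r$lengths >= minGutter &
                   starts > 1L & ends < length(white))
    cbind(starts[idx], ends[idx])
  }
  rows <- gutterRuns(rowWhite)
  cols <- gutterRuns(colWhite)
  segments <- function(runs, n) {
    cuts <- c(0L, as.vector(t(cbind(runs[, 1] - 1L, runs[, 2]))), n)
    m <- matrix(cuts, ncol = 2, byrow = TRUE)
    m[m[, 2] > m[, 1], , drop = FALSE]
  }
  if (nrow(rows) > 0) {
    out <- list()
    for (s in seq_len(nrow(segments(rows, h)))) {
      seg <- segments(rows, h)[s, ]
      out <- c(out, splitAtGutters(gray[(seg[1] + 1):seg[2], , drop = FALSE],
                                   offX, offY + seg[1], minGutter, whiteLevel))
    }
    return(out)
  }
  if (nrow(cols) > 0) {
    out <- list()
    for (s in seq_len(nrow(segments(cols, w)))) {
      seg <- segments(cols, w)[s, ]
      out <- c(out, splitAtGutters(gray[, (seg[1] + 1):seg[2], drop = FALSE],
                                   offX + seg[1], offY, minGutter, whiteLevel))
    }
    return(out)
  }
  # leaf: trim white margins
  nr <- which(!rowWhite); nc <- which(!colWhite)
  list(c(offX + nc[1] - 1L, offY + nr[1] - 1L,
         offX + nc[length(nc)], offY + nr[length(nr)]))
}

# reading-order permutation of a box data.frame: boxes are bucketed into
# rows (a new row starts when a box begins below every box of the current
# row), rows ordered top to bottom, boxes within a row left to right
readingOrder <- function(boxes) {
  cx <- (boxes$x0 + boxes$x1) / 2
  ord <- order(boxes$y0, cx)
  rows <- integer(nrow(boxes))
  rowid <- 0L
  lastY1 <- -Inf
  for (i in ord) {
    if (boxes$y0[i] >= lastY1) {
      rowid <- rowid + 1L
      lastY1 <- boxes$y1[i]
    } else lastY1 <- max(lastY1, boxes$y1[i])
    rows[i] <- rowid
  }
  order(rows, cx, boxes$y0)
}

#' Crop detected panels and filter them to the types of interest
#'
#' Panels typed graphs-and-plots are excluded by default (analytically
#' generated charts look alike across unrelated data and flood the analysis
#' with false matches), as are panels smaller than `minSize`. Panel ids are
#' assigned in reading order (top-left to bottom-right by box center) over
#' the full, unfiltered box set, so ids are a pure function of the figure and
#' its sorted boxes.
#'
#' @param figure a \linkS4class{FigureImage}.
#' @param boxes box data.frame from [detectPanels()].
#' @param allowedTypes panel types forwarded to provenance analysis.
#' @param minSize minimum panel width and height in pixels (default 64).
#' @return list of \linkS4class{Panel}.
#' @export
cropAndFilter <- function(figure, boxes,
                          allowedTypes = c("microscopy", "blots",
                                           "body_imaging", "flow_cytometry"),
                          minSize = 64L) {
  if (nrow(boxes) == 0) return(list())
  boxes <- boxes[readingOrder(boxes), , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(boxes))) {
    b <- boxes[k, ]
    if (!(b$type %in% allowedTypes)) next
    if (b$x1 - b$x0 < minSize || b$y1 - b$y0 < minSize) next
    raster <- figure@raster[(b$y0 + 1):b$y1, (b$x0 + 1):b$x1, , drop = FALSE]
    out[[length(out) + 1L]] <-
      new("Panel", panelId = sprintf("%s/p%d", figure@figureId, k),
          docId = figure@docId, figureId = figure@figureId,
          bbox = as.numeric(c(b$x0, b$y0, b$x1, b$y1)),
          panelType = b$type, raster = raster)
  }
  out
}

#' Read a corpus annotation file
#'
#' Parses the JSON annotation schema: a list of documents, each with figures
#' carrying a file reference and panel records (bbox, type, optional group
#' label for annotated reuse).
#'
#' @param path path to the JSON file (e.g. the `truth.json` written by
#'   [generateCorpus()]).
#' @return the parsed annotation list.
#' @export
readAnnotations <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE) |> normalizeAnnotations()
}

normalizeAnnotations <- function(ann) {
  docs <- ann$documents %||% ann
  docs <- lapply(docs, function(d) {
    d$figures <- lapply(d$figures, function(fg) {
      fg$panels <- lapply(fg$panels, function(p) {
        p$bbox <- as.numeric(unlist(p$bbox))
        p
      })
      fg
    })
    d
  })
  ann$documents <- docs
  ann
}

#' Ingest a full corpus of figures into panels
#'
#' Convenience wrapper: extracts figures for every document, detects panels
#' with the chosen backend, and crops/filters them.
#'
#' @param figureDir directory of figure files named "<doc_id>_fig<k>.<ext>"
#'   (as written by [generateCorpus()]), or NULL when `pdfDir` is given.
#' @param pdfDir directory of one PDF per document (alternative input).
#' @param annotations annotation list or path to its JSON file.
#' @param backend detector backend, see [detectPanels()].
#' @param allowedTypes,minSize forwarded to [cropAndFilter()].
#' @return named list of \linkS4class{Panel} keyed by panel id.
#' @export
ingestCorpus <- function(figureDir = NULL, pdfDir = NULL, annotations = NULL,
                         backend = c("annotation", "heuristic", "model"),
                         allowedTypes = c("microscopy", "blots",
                                          "body_imaging", "flow_cytometry"),
                         minSize = 64L) {
  backend <- match.arg(backend)
  if (is.character(annotations)) annotations <- readAnnotations(annotations)
  figures <- list()
  if (!is.null(figureDir)) {
    files <- sort(list.files(figureDir, pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      stem <- sub("\\.[A-Za-z]+$", "", basename(f))
      m <- regmatches(stem, regexec("^(.*)_fig(\\d+)$", stem))[[1]]
      if (length(m) == 3) { docId <- m[2]; k <- as.integer(m[3]) }
      else { docId <- stem; k <- 1L }
      figures[[length(figures) + 1L]] <-
        new("FigureImage", figureId = sprintf("%s/fig%d", docId, k),
            docId = docId, raster = asRGB(readRasterFile(f)))
    }
  } else if (!is.null(pdfDir)) {
    pdfs <- sort(list.files(pdfDir, pattern = "\\.pdf$", full.names = TRUE))
    for (p in pdfs) figures <- c(figures, extractFigures(p))
  } else stop("provide figureDir or pdfDir")
  panels <- list()
  for (fig in figures) {
    boxes <- detectPanels(fig, backend = backend, annotations = annotations)
    for (p in cropAndFilter(fig, boxes, allowedTypes = allowedTypes,
                            minSize = minSize))
      panels[[p@panelId]] <- p
  }
  panels
}
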