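# Synthetic corpus generator: procedural panels of the five types, planted
# cross-document reuse under parameterized transformation chains, compound
# figure composition, and ground-truth annotations. All randomness flows
# through R's RNG seeded from the FixtureSpec, so a spec yields a
# byte-identical corpus on any platform.

# draw an anisotropic Gaussian blob onto an h x w x 3 array (in place value)
addBlob <- function(img, cx, cy, r, color, amp = 1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- max(1, floor(cx - 3 * r + 1)); x1 <- min(w, ceiling(cx + 3 * r + 1))
  y0 <- max(1, floor(cy - 3 * r + 1)); y1 <- min(h, ceiling(cy + 3 * r + 1))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  g <- exp(-outer((ys - 1 - cy)^2, (xs - 1 - cx)^2, "+") / (2 * r^2))
  for (ch in 1:3)
    img[ys, xs, ch] <- img[ys, xs, ch] + amp * color[ch] * g
  img
}

blobField <- function(width, height, n, bg, rRange, palette, ampRange) {
  img <- array(rep(bg, each = height * width), dim = c(height, width, 3))
  for (i in seq_len(n)) {
    col <- palette[[sample.int(length(palette), 1)]]
    img <- addBlob(img,
                   cx = runif(1, 1, width - 2), cy = runif(1, 1, height - 2),
                   r = runif(1, rRange[1], rRange[2]), color = col,
                   amp = runif(1, ampRange[1], ampRange[2]) * sample(c(-1, 1), 1))
  }
  clamp01(img)
}

#' Generate a procedural panel raster of a given type
#'
#' Procedural stand-ins for the five biomedical panel types: microscopy
#' panels are dense textured blob fields (keypoint rich), blots are
#' low-entropy dark bands on a blurred light background, body imaging panels
#' are smooth gradient anatomy-like shapes, flow cytometry panels are sparse
#' scatter clouds on a white background, and graphs are axes with bars.
#' Draws from the current RNG state; seed it for reproducibility.
#'
#' @param type one of the five panel types.
#' @param width,height panel size in pixels.
#' @return an h x w x 3 numeric array in [0, 1].
#' @export
synthPanel <- function(type = c("microscopy", "blots", "body_imaging",
                                "graphs_plots", "flow_cytometry"),
                       width = 180, height = 140) {
  type <- match.arg(type)
  w <- width; h <- height
  img <- switch(type,
    microscopy = {
      bg <- c(runif(1, 0.05, 0.25), runif(1, 0.05, 0.2), runif(1, 0.1, 0.3))
      pal <- list(c(0.8, 0.3, 0.7), c(0.6, 0.8, 0.3), c(0.9, 0.6, 0.2),
                  c(0.4, 0.7, 0.9))
      out <- blobField(w, h, n = round(w * h / 180), bg = bg,
                       rRange = c(1.5, 6), palette = pal, ampRange = c(0.3, 0.9))
      out + array(rnorm(h * w * 3, 0, 0.015), dim = c(h, w, 3))
    },
    blots = {
      base <- runif(1, 0.78, 0.9)
      grad <- outer(seq(0, 0.05, length.out = h), seq(0, 0.03, length.out = w), "+")
      out <- array(rep(base - grad, 3), dim = c(h, w, 3))
      nb <- sample(3:5, 1)
      for (i in seq_len(nb)) {
        cy <- runif(1, 0.15, 0.85) * h
        cx <- runif(1, 0.2, 0.8) * w
        bw <- runif(1, 0.15, 0.3) * w
        bh <- runif(1, 0.03, 0.06) * h
        dark <- runif(1, 0.35, 0.6)
        ys <- seq_len(h) - 1; xs <- seq_len(w) - 1
        band <- outer(exp(-((ys - cy) / bh)^4), exp(-((xs - cx) / bw)^4))
        for (ch in 1:3) out[, , ch] <- out[, , ch] - dark * band
      }
      blurRaster(clamp01(out), sigma = 2.2)
    },
    body_imaging = {
      out <- array(runif(1, 0.02, 0.08), dim = c(h, w, 3))
      ys <- seq_len(h) - 1; xs <- seq_len(w) - 1
      for (i in seq_len(3)) {
        cx <- runif(1, 0.3, 0.7) * w; cy <- runif(1, 0.3, 0.7) * h
        rx <- runif(1, 0.15, 0.4) * w; ry <- runif(1, 0.15, 0.4) * h
        lev <- runif(1, 0.3, 0.8)
        d <- outer((ys - cy)^2 / ry^2, (xs - cx)^2 / rx^2, "+")
        shape <- lev * exp(-d * 1.5)
        for (ch in 1:3) out[, , ch] <- out[, , ch] + shape
      }
      blurRaster(clamp01(out), sigma = 3)
    },
    flow_cytometry = {
      out <- array(1, dim = c(h, w, 3))
      # axes along the left and bottom margins
      out[, 1:2, ] <- 0.2
      out[(h - 1):h, , ] <- 0.2
      nclust <- sample(2:3, 1)
      for (k in seq_len(nclust)) {
        cx <- runif(1, 0.25, 0.8) * w; cy <- runif(1, 0.2, 0.7) * h
        sx <- runif(1, 0.04, 0.09) * w; sy <- runif(1, 0.04, 0.09) * h
        npts <- round(0.12 * w * h / nclust / 8)
        px <- pmin(pmax(round(rnorm(npts, cx, sx)), 4), w - 2)
        py <- pmin(pmax(round(rnorm(npts, cy, sy)), 2), h - 4)
        col <- c(runif(1, 0, 0.3), runif(1, 0, 0.3), runif(1, 0.3, 0.8))
        for (i in seq_len(npts))
          for (ch in 1:3) out[py[i] + (0:1), px[i] + (0:1), ch] <- col[ch]
      }
      out
    },
    graphs_plots = {
      out <- array(1, dim = c(h, w, 3))
      out[, 3:4, ] <- 0
      out[(h - 3):(h - 2), , ] <- 0
      nbar <- sample(4:6, 1)
      bw <- floor((w - 12) / nbar)
      col <- c(runif(1, 0.1, 0.9), runif(1, 0.1, 0.9), runif(1, 0.1, 0.9))
      for (b in seq_len(nbar)) {
        bh <- round(runif(1, 0.2, 0.85) * (h - 10))
        x0 <- 6 + (b - 1) * bw
        for (ch in 1:3)
          out[(h - 4 - bh):(h - 4), (x0 + 1):(x0 + bw - 3), ch] <- col[ch]
      }
      out
    })
  clamp01(img)
}

# Gaussian blur of an h x w x 3 array via the package's separable kernel
blurRaster <- function(raster, sigma) {
  for (ch in 1:3) raster[, , ch] <- .gaussian_blur(raster[, , ch], sigma)
  raster
}

# bilinear resize of an h x w x 3 array
resizeRaster <- function(raster, width, height) {
  out <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) out[, , ch] <- .resize_bilinear(raster[, , ch], width, height)
  clamp01(out)
}

#' Apply one transformation operation to a panel raster
#'
#' Supported kinds: crop (params: x0, y0, w, h in pixels), rescale (factor),
#' hflip, vflip, color_shift (shift: length-3 offsets), jpeg_recompress
#' (quality in 1..100), gaussian_noise (sigma; deterministic given the RNG
#' state), splice_onto_background (bg: background gray level, pad: pixels).
#'
#' @param raster h x w x 3 array.
#' @param op list(kind = ..., ...parameters...).
#' @return transformed raster.
#' @export
applyTransform <- function(raster, op) {
  switch(op$kind,
    crop = raster[(op$y0 + 1):(op$y0 + op$h), (op$x0 + 1):(op$x0 + op$w), ,
                  drop = FALSE],
    rescale = resizeRaster(raster,
                           width = max(8, round(dim(raster)[2] * op$factor)),
                           height = max(8, round(dim(raster)[1] * op$factor))),
    hflip = flipRaster(raster, "horizontal"),
    vflip = flipRaster(raster, "vertical"),
    color_shift = clamp01(sweep(raster, 3, op$shift, "+")),
    gaussian_noise = clamp01(raster + array(rnorm(length(raster), 0, op$sigma),
                                            dim = dim(raster))),
    jpeg_recompress = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("jpeg package required for jpeg_recompress")
      f <- tempfile(fileext = ".jpg")
      on.exit(unlink(f))
      jpeg::writeJPEG(raster, f, quality = op$quality / 100)
      asRGB(jpeg::readJPEG(f))
    },
    splice_onto_background = {
      d <- dim(raster)
      out <- array(op$bg, dim = c(d[1] + 2 * op$pad, d[2] + 2 * op$pad, 3))
      out[op$pad + seq_len(d[1]), op$pad + seq_len(d[2]), ] <- raster
      out
    },
    stop("unknown transform kind: ", op$kind))
}

# draw a concrete transformation chain for one reuse instance; returns the
# resolved ops (exact parameters recorded for ground truth)
drawTransformChain <- function(srcDim, tp) {
  ops <- list()
  if (tp$cropFrac < 1) {
    side <- sqrt(tp$cropFrac)
    w2 <- round(srcDim[2] * side); h2 <- round(srcDim[1] * side)
    # jittered central anchor keeps pairwise crop overlap high
    x0 <- round((srcDim[2] - w2) * runif(1, 0.35, 0.65))
    y0 <- round((srcDim[1] - h2) * runif(1, 0.35, 0.65))
    ops <- c(ops, list(list(kind = "crop", x0 = x0, y0 = y0, w = w2, h = h2)))
  }
  s <- runif(1, tp$scaleRange[1], tp$scaleRange[2])
  ops <- c(ops, list(list(kind = "rescale", factor = s)))
  if (runif(1) < tp$flipProb)
    ops <- c(ops, list(list(kind = "hflip")))
  shift <- rnorm(3, 0, tp$colorSigma)
  ops <- c(ops, list(list(kind = "color_shift", shift = shift)))
  if (tp$noiseSigma > 0)
    ops <- c(ops, list(list(kind = "gaussian_noise", sigma = tp$noiseSigma)))
  if (!is.null(tp$jpegQuality))
    ops <- c(ops, list(list(kind = "jpeg_recompress", quality = tp$jpegQuality)))
  ops
}

#' Specification of a synthetic corpus
#'
#' The defaults produce the standard study corpus: 30 documents of which 5
#' are "mill" documents, 2 figures per document, 4 panels per figure, and 3
#' reuse groups planted across the mill documents under the default
#' transformation chain (central crop to 75% of the area, rescale 0.75-1.3,
#' mirroring with probability 0.5, small color shift and Gaussian noise, and
#' JPEG recompression at quality 85 — magnitudes within the robustness
#' envelope the descriptors and matcher are designed for).
#'
#' @param seed integer RNG seed.
#' @param nDocuments,nMillDocuments corpus size and number of mill documents.
#' @param figuresPerDocument,panelsPerFigure compound-figure structure.
#' @param typeMix named probability vector over panel types for distractor
#'   panels.
#' @param reuseGroups list of list(label, size, type); instances are planted
#'   round-robin across the mill documents.
#' @param transformParams list(cropFrac, scaleRange, flipProb, colorSigma,
#'   noiseSigma, jpegQuality); jpegQuality = NULL disables recompression.
#' @return a list with class "FixtureSpec".
#' @export
fixtureSpec <- function(seed = 1L,
                        nDocuments = 30L, nMillDocuments = 5L,
                        figuresPerDocument = 2L, panelsPerFigure = 4L,
                        typeMix = c(microscopy = 0.4, blots = 0.15,
                                    body_imaging = 0.15, graphs_plots = 0.15,
                                    flow_cytometry = 0.15),
                        reuseGroups = list(
                          list(label = "MG1", size = 3L, type = "microscopy"),
                          list(label = "MG2", size = 4L, type = "microscopy"),
                          list(label = "FC1", size = 3L, type = "flow_cytometry")),
                        transformParams = list(cropFrac = 0.75,
                                               scaleRange = c(0.75, 1.3),
                                               flipProb = 0.5,
                                               colorSigma = 0.03,
                                               noiseSigma = 0.008,
                                               jpegQuality = 85)) {
  if (nMillDocuments > nDocuments)
    stop("nMillDocuments must not exceed nDocuments")
  millSlots <- nMillDocuments * figuresPerDocument * panelsPerFigure
  need <- sum(vapply(reuseGroups, function(g) as.integer(g$size), integer(1)))
  if (need > millSlots)
    stop("infeasible spec: reuse groups need ", need, " panel slots but mill ",
         "documents provide only ", millSlots)
  spec <- list(seed = as.integer(seed), nDocuments = as.integer(nDocuments),
               nMillDocuments = as.integer(nMillDocuments),
               figuresPerDocument = as.integer(figuresPerDocument),
               panelsPerFigure = as.integer(panelsPerFigure),
               typeMix = typeMix, reuseGroups = reuseGroups,
               transformParams = transformParams)
  class(spec) <- "FixtureSpec"
  spec
}

#' Generate a synthetic corpus with planted cross-document panel reuse
#'
#' Writes one PNG per compound figure plus `truth.json` (annotation schema:
#' per-document figure/panel boxes with types and group labels, group
#' memberships, suspicious sets and the exact planted transformation
#' parameters). Mill documents receive the reuse-group instances; distractor
#' documents receive only fresh panels. Deterministic: the same spec produces
#' a byte-identical corpus.
#'
#' @param spec a [fixtureSpec()].
#' @param outDir output directory (created if needed).
#' @param pdf logical; additionally write one single-figure-per-page PDF per
#'   document under `pdfs/`.
#' @return invisibly, the path to `truth.json`.
#' @export
generateCorpus <- function(spec, outDir, pdf = FALSE) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(file.path(outDir, "figures"), recursive = TRUE, showWarnings = FALSE)
  if (pdf) dir.create(file.path(outDir, "pdfs"), showWarnings = FALSE)
  withLocalSeed(spec$seed, {
    docIds <- sprintf("doc%03d", seq_len(spec$nDocuments))
    millDocs <- docIds[seq_len(spec$nMillDocuments)]
    fpd <- spec$figuresPerDocument; ppf <- spec$panelsPerFigure

    # plan panel slots: slot key = (doc, fig, pos)
    slots <- expand.grid(pos = seq_len(ppf), fig = seq_len(fpd),
                         doc = docIds, stringsAsFactors = FALSE)[, 3:1]
    slots$assigned <- NA_character_  # group label or NA (distractor)
    slots$instance <- NA_integer_

    # round-robin instance placement over mill documents: one instance per
    # document where possible, overflowing to further slots
    millSlotIdx <- which(slots$doc %in% millDocs)
    millSlotIdx <- millSlotIdx[order(match(slots$doc[millSlotIdx], millDocs),
                                     slots$fig[millSlotIdx], slots$pos[millSlotIdx])]
    # order mill slots so consecutive picks rotate across documents
    byDoc <- split(millSlotIdx, slots$doc[millSlotIdx])
    rotation <- integer(0)
    while (any(lengths(byDoc) > 0)) {
      for (d in millDocs) {
        if (length(byDoc[[d]]) > 0) {
          rotation <- c(rotation, byDoc[[d]][1])
          byDoc[[d]] <- byDoc[[d]][-1]
        }
      }
    }
    cursor <- 1L
    for (g in spec$reuseGroups) {
      for (inst in seq_len(g$size)) {
        idx <- rotation[cursor]; cursor <- cursor + 1L
        slots$assigned[idx] <- g$label
        slots$instance[idx] <- inst
      }
    }

    # source rasters for the reuse groups
    groupSrc <- list()
    groupType <- character(0)
    for (g in spec$reuseGroups) {
      groupSrc[[g$label]] <- synthPanel(g$type, width = 220, height = 170)
      groupType[g$label] <- g$type
    }

    truthDocs <- list()
    transforms <- list()
    groupMembers <- stats::setNames(vector("list", length(groupSrc)),
                                    names(groupSrc))
    gutter <- 12L

    for (d in docIds) {
      figs <- list()
      for (f in seq_len(fpd)) {
        figureId <- sprintf("%s/fig%d", d, f)
        rows <- slots[slots$doc == d & slots$fig == f, ]
        panels <- vector("list", nrow(rows))
        types <- character(nrow(rows))
        groups <- rep(NA_character_, nrow(rows))
        for (i in seq_len(nrow(rows))) {
          if (!is.na(rows$assigned[i])) {
            lab <- rows$assigned[i]
            types[i] <- groupType[lab]
            groups[i] <- lab
            src <- groupSrc[[lab]]
            if (rows$instance[i] == 1L) {
              panels[[i]] <- src
              transforms <- c(transforms, list(list(
                figure = figureId, position = i, group = lab, ops = list())))
            } else {
              ops <- drawTransformChain(dim(src), spec$transformParams)
              out <- src
              for (op in ops) out <- applyTransform(out, op)
              panels[[i]] <- out
              transforms <- c(transforms, list(list(
                figure = figureId, position = i, group = lab, ops = ops)))
            }
          } else {
            types[i] <- sample(names(spec$typeMix), 1, prob = spec$typeMix)
            panels[[i]] <- synthPanel(types[i],
                                      width = sample(150:220, 1),
                                      height = sample(120:180, 1))
          }
        }
        # compose a compound figure: row-major grid, white gutters
        ncols <- ceiling(sqrt(length(panels)))
        nrows <- ceiling(length(panels) / ncols)
        cellW <- max(vapply(panels, function(p) dim(p)[2], integer(1)))
        cellH <- max(vapply(panels, function(p) dim(p)[1], integer(1)))
        figW <- ncols * cellW + (ncols + 1) * gutter
        figH <- nrows * cellH + (nrows + 1) * gutter
        fig <- array(1, dim = c(figH, figW, 3))
        boxes <- matrix(0, nrow = length(panels), ncol = 4)
        for (i in seq_along(panels)) {
          r <- (i - 1) %/% ncols; cc <- (i - 1) %% ncols
          x0 <- gutter + cc * (cellW + gutter)
          y0 <- gutter + r * (cellH + gutter)
          ph <- dim(panels[[i]])[1]; pw <- dim(panels[[i]])[2]
          fig[(y0 + 1):(y0 + ph), (x0 + 1):(x0 + pw), ] <- panels[[i]]
          boxes[i, ] <- c(x0, y0, x0 + pw, y0 + ph)
        }
        file <- sprintf("figures/%s_fig%d.png", d, f)
        png::writePNG(fig, file.path(outDir, file))
        # panel ids follow ingest's deterministic reading order: reorder the
        # records with the same permutation cropAndFilter uses
        perm <- readingOrder(data.frame(x0 = boxes[, 1], y0 = boxes[, 2],
                                        x1 = boxes[, 3], y1 = boxes[, 4]))
        boxes <- boxes[perm, , drop = FALSE]
        types <- types[perm]
        groups <- groups[perm]
        panelRecords <- lapply(seq_along(panels), function(i) {
          rec <- list(bbox = as.integer(boxes[i, ]), type = types[i])
          if (!is.na(groups[i])) rec$group <- groups[i]
          rec
        })
        for (i in seq_along(panels)) {
          if (!is.na(groups[i])) {
            pid <- sprintf("%s/p%d", figureId, i)
            groupMembers[[groups[i]]] <- c(groupMembers[[groups[i]]], pid)
          }
        }
        figs[[f]] <- list(figure_id = figureId, file = file,
                          panels = panelRecords)
      }
      truthDocs[[d]] <- list(doc_id = d, figures = figs)
      if (pdf) {
        rasters <- lapply(figs, function(fg)
          asRGB(png::readPNG(file.path(outDir, fg$file))))
        writeMiniPdf(rasters, file.path(outDir, "pdfs", paste0(d, ".pdf")))
      }
    }

    suspiciousPanels <- sort(unique(unlist(groupMembers)))
    suspiciousDocs <- sort(unique(sub("/.*$", "", suspiciousPanels)))
    truth <- list(
      documents = unname(truthDocs),
      groups = lapply(names(groupMembers), function(lab)
        list(label = lab, type = groupType[[lab]],
             members = groupMembers[[lab]])),
      suspicious_panels = suspiciousPanels,
      suspicious_documents = suspiciousDocs,
      transforms = transforms,
      seed = spec$seed)
    truthPath <- file.path(outDir, "truth.json")
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"), truthPath)
    invisible(truthPath)
  })
}

#' Construct the 50%-crop worked example
#'
#' Builds a source panel R and a crop P covering exactly half of R's area.
#' `constructed = TRUE` returns, in addition, a MatchResult whose matched
#' points are a corner-to-corner grid over P (mapped into R by the known crop
#' offset), for which the directional content-sharing scores are exactly 1.0
#' and 0.5 by construction. With `constructed = FALSE` only the panel pair is
#' returned, for running the full pixel pipeline: the crop window is filled
#' with dense texture (strong features reaching into its corners) and is
#' surrounded by a flat band so near-border interest points survive the crop.
#'
#' @param seed RNG seed for the texture.
#' @param constructed logical, see above.
#' @return list(P, R, offset, and — when constructed — match).
#' @export
makeCrop50Pair <- function(seed = 1L, constructed = FALSE) {
  if (constructed) {
    W <- 200L; H <- 100L; w2 <- 100L; h2 <- 100L; ox <- 60L; oy <- 0L
    raster <- array(0.5, dim = c(H, W, 3))
    R <- new("Panel", panelId = "ex/fig1/p1", docId = "exR", figureId = "ex/fig1",
             bbox = c(0, 0, W, H), panelType = "microscopy", raster = raster)
    P <- new("Panel", panelId = "ex/fig2/p1", docId = "exP", figureId = "ex/fig2",
             bbox = c(0, 0, w2, h2), panelType = "microscopy",
             raster = raster[(oy + 1):(oy + h2), (ox + 1):(ox + w2), , drop = FALSE])
    gx <- seq(0, w2 - 1, length.out = 5)
    gy <- seq(0, h2 - 1, length.out = 5)
    pts <- as.matrix(expand.grid(x = gx, y = gy))
    match <- matchResult(P@panelId, R@panelId,
                         inlierP = pts,
                         inlierR = cbind(pts[, 1] + ox, pts[, 2] + oy),
                         homography = matrix(c(1, 0, ox, 0, 1, oy, 0, 0, 1),
                                             3, 3, byrow = TRUE))
    return(list(P = P, R = R, offset = c(ox, oy), match = match))
  }
  withLocalSeed(seed, {
    W <- 900L; H <- 600L; w2 <- 600L; h2 <- 450L; ox <- 150L; oy <- 75L
    band <- 16L   # flat band around the crop window (same color as the frame)
    inset <- 10L  # flat frame width inside the crop window
    bgc <- c(0.16, 0.13, 0.2)
    raster <- array(rep(bgc, each = H * W), dim = c(H, W, 3))
    # crop window: flat frame, dense texture inset from the border
    tex <- array(rep(bgc, each = h2 * w2), dim = c(h2, w2, 3))
    core <- blobField(w2 - 2L * inset, h2 - 2L * inset,
                      n = round(w2 * h2 / 300),
                      bg = bgc, rRange = c(1.5, 5),
                      palette = list(c(0.8, 0.3, 0.7), c(0.5, 0.8, 0.3),
                                     c(0.9, 0.6, 0.2)),
                      ampRange = c(0.3, 0.9))
    tex[(inset + 1):(h2 - inset), (inset + 1):(w2 - inset), ] <- core
    # a distinct small blob cluster at each corner of the crop window: the
    # corner-most blob anchors the matched hull at the corner, the random
    # companions make each corner's descriptor unique
    corners <- list(c(2, 2), c(w2 - 3, 2), c(2, h2 - 3), c(w2 - 3, h2 - 3))
    # fixed companion patterns, distinct per corner, so each corner's
    # descriptor is unambiguous under the ratio test
    companions <- list(list(c(9, 6, 1.5), c(6, 12, 2.0)),
                       list(c(12, 7, 1.4), c(7, 7, 2.1)),
                       list(c(6, 9, 1.8), c(13, 13, 1.4)),
                       list(c(8, 13, 1.6), c(14, 8, 1.9)))
    for (ci in seq_along(corners)) {
      corner <- corners[[ci]]
      tex <- addBlob(tex, corner[1], corner[2], r = 2,
                     color = c(1, 1, 0.6), amp = 0.55)
      for (cp in companions[[ci]]) {
        dx <- cp[1] * sign(w2 / 2 - corner[1])
        dy <- cp[2] * sign(h2 / 2 - corner[2])
        tex <- addBlob(tex, corner[1] + dx, corner[2] + dy, r = cp[3],
                       color = c(1, 1, 0.6), amp = 0.45)
      }
    }
    tex <- clamp01(tex)
    raster[(oy + 1):(oy + h2), (ox + 1):(ox + w2), ] <- tex
    # sparse unrelated texture outside the flat band
    far <- blobField(W, H, n = 250, bg = bgc, rRange = c(2, 5),
                     palette = list(c(0.3, 0.5, 0.7), c(0.7, 0.4, 0.3)),
                     ampRange = c(0.2, 0.6))
    outer_mask <- matrix(TRUE, H, W)
    outer_mask[max(1, oy - band + 1):min(H, oy + h2 + band),
               max(1, ox - band + 1):min(W, ox + w2 + band)] <- FALSE
    for (ch in 1:3) {
      tmp <- raster[, , ch]
      tmp[outer_mask] <- far[, , ch][outer_mask]
      raster[, , ch] <- tmp
    }
    R <- new("Panel", panelId = "ex/fig1/p1", docId = "exR", figureId = "ex/fig1",
             bbox = c(0, 0, W, H), panelType = "microscopy", raster = raster)
    P <- new("Panel", panelId = "ex/fig2/p1", docId = "exP", figureId = "ex/fig2",
             bbox = c(0, 0, w2, h2), panelType = "microscopy",
             raster = raster[(oy + 1):(oy + h2), (ox + 1):(ox + w2), , drop = FALSE])
    list(P = P, R = R, offset = c(ox, oy))
  })
}

#' Affine-resampled copy of a panel raster with known ground truth
#'
#' Produces a rescaled / rotated / mirrored copy by inverse bilinear
#' resampling (out-of-bounds reads clamp to the edge), together with the
#' 3 x 3 homography that maps source coordinates to the copy. Used to plant
#' pairs whose alignment parameters are known exactly, so the matcher's
#' recovered homography can be checked against them.
#'
#' @param raster h x w x 3 source array.
#' @param scale isotropic scale factor.
#' @param theta rotation angle in degrees (counter-clockwise, about the
#'   center).
#' @param flip logical; mirror horizontally after the rotation/scale.
#' @return list(raster, H) where H maps source (x, y, 1) to copy pixels.
#' @export
affineResample <- function(raster, scale = 1, theta = 0, flip = FALSE) {
  h <- dim(raster)[1]; w <- dim(raster)[2]
  w2 <- max(8L, round(w * scale)); h2 <- max(8L, round(h * scale))
  th <- theta * pi / 180
  # forward map: center, rotate, scale, re-center (then optional mirror)
  A <- scale * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                      byrow = TRUE)
  t0 <- c((w2 - 1) / 2, (h2 - 1) / 2) - A %*% c((w - 1) / 2, (h - 1) / 2)
  H <- rbind(cbind(A, t0), c(0, 0, 1))
  if (flip) {
    Fm <- matrix(c(-1, 0, w2 - 1, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    H <- Fm %*% H
  }
  Hinv <- solve(H)
  xs <- matrix(rep(0:(w2 - 1), each = h2), h2, w2)
  ys <- matrix(rep(0:(h2 - 1), times = w2), h2, w2)
  u <- Hinv[1, 1] * xs + Hinv[1, 2] * ys + Hinv[1, 3]
  v <- Hinv[2, 1] * xs + Hinv[2, 2] * ys + Hinv[2, 3]
  u0 <- floor(u); v0 <- floor(v)
  du <- u - u0; dv <- v - v0
  cl <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  i00 <- cbind(as.vector(cl(v0, 0, h - 1)) + 1, as.vector(cl(u0, 0, w - 1)) + 1)
  i01 <- cbind(as.vector(cl(v0, 0, h - 1)) + 1, as.vector(cl(u0 + 1, 0, w - 1)) + 1)
  i10 <- cbind(as.vector(cl(v0 + 1, 0, h - 1)) + 1, as.vector(cl(u0, 0, w - 1)) + 1)
  i11 <- cbind(as.vector(cl(v0 + 1, 0, h - 1)) + 1, as.vector(cl(u0 + 1, 0, w - 1)) + 1)
  out <- array(0, dim = c(h2, w2, 3))
  for (ch in 1:3) {
    pl <- raster[, , ch]
    val <- (1 - dv) * ((1 - du) * matrix(pl[i00], h2, w2) +
                         du * matrix(pl[i01], h2, w2)) +
      dv * ((1 - du) * matrix(pl[i10], h2, w2) +
              du * matrix(pl[i11], h2, w2))
    out[, , ch] <- val
  }
  list(raster = clamp01(out), H = H)
}
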