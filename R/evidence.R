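# Panel descriptors and similarity retrieval. The default backend is a
# deterministic, weight-free image hash: the panel is flip-canonicalized,
# downscaled to a fixed grid, and described by low-frequency DCT coefficients
# of the contrast-normalized grayscale plus a coarse color histogram. This is
# robust (in the ranking sense) to rescaling, mirroring, recompression, mild
# color shifts and moderate crops. A convolutional backend can be plugged in
# as a function for deployments with a pretrained network available.

DESC_GRID <- 64L
DCT_KEEP <- 8L

dctMatrix <- function(n) {
  i <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(i, 2 * i + 1) / (2 * n))
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Compute the evidence descriptor of a panel
#'
#' @param panel a \linkS4class{Panel} or h x w x 3 raster.
#' @param backend "hash" (deterministic built-in, default) or "conv"
#'   (requires `convFn`).
#' @param convFn for the conv backend: a function(raster) returning a numeric
#'   vector (e.g. a pretrained network's penultimate-layer features).
#'   Requesting conv without one is a configuration error.
#' @return a list with class "PanelDescriptor": `panel_id`, L2-normalized
#'   `vector`, `backend`, `dim`.
#' @export
describePanel <- function(panel, backend = c("hash", "conv"), convFn = NULL) {
  backend <- match.arg(backend)
  raster <- if (is(panel, "Panel")) panel@raster else panel
  v <- if (backend == "hash") {
    hashDescriptor(raster)
  } else {
    if (!is.function(convFn))
      stop("conv backend requested but no network supplied; ",
           "use backend = \"hash\" for the built-in descriptor")
    as.numeric(convFn(raster))
  }
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) v[1] <- 1 else v <- v / nrm
  out <- list(panel_id = if (is(panel, "Panel")) panel@panelId else NA_character_,
              vector = v, backend = backend, dim = length(v))
  class(out) <- "PanelDescriptor"
  out
}

hashDescriptor <- function(raster) {
  raster <- asRGB(raster)
  gray <- toGray(raster)
  # anti-alias before downsampling so rescaled copies land on the same grid
  shrink <- sqrt(prod(dim(gray)) / DESC_GRID^2)
  if (shrink > 1) gray <- .gaussian_blur(gray, 0.5 * shrink)
  g <- .resize_bilinear(gray, DESC_GRID, DESC_GRID)
  s <- stats::sd(g)
  gs <- if (s > 1e-8) (g - mean(g)) / s else g * 0
  D <- dctMatrix(DESC_GRID)
  coef <- (D %*% gs %*% t(D))[seq_len(DCT_KEEP), seq_len(DCT_KEEP)]
  # flip canonicalization: mirroring only flips the signs of odd-frequency
  # coefficients, so coefficient magnitudes are exactly mirror-invariant
  dct <- abs(as.vector(coef)[-1])  # drop the DC term
  hist <- unlist(lapply(1:3, function(ch)
    tabulate(pmin(floor(raster[, , ch] * 8) + 1, 8), nbins = 8)))
  hist <- hist / max(sum(hist), 1)
  c(dct, 4 * hist)
}

#' Build an evidence database from a set of panels
#'
#' @param panels named list of \linkS4class{Panel} (e.g. from
#'   [ingestCorpus()]).
#' @param backend,convFn see [describePanel()].
#' @return an \linkS4class{EvidenceDB}.
#' @export
buildEvidenceDB <- function(panels, backend = "hash", convFn = NULL) {
  ids <- unname(vapply(panels, function(p) p@panelId, character(1)))
  ord <- order(ids)
  panels <- panels[ord]; ids <- ids[ord]
  vecs <- t(vapply(panels, function(p)
    describePanel(p, backend = backend, convFn = convFn)$vector,
    numeric(describePanel(panels[[1]], backend = backend,
                          convFn = convFn)$dim)))
  rownames(vecs) <- ids
  meta <- data.frame(panel_id = ids,
                     doc_id = unname(vapply(panels, function(p) p@docId,
                                            character(1))),
                     panel_type = unname(vapply(panels, function(p) p@panelType,
                                                character(1))),
                     stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  new("EvidenceDB", vectors = vecs, meta = meta, backend = backend)
}

#' Retrieve the most similar panels to a query
#'
#' Candidates are restricted to panels of the same type as the query; panels
#' from the query's own source document (and the query itself) are excluded —
#' the goal is reuse across different documents. Results are sorted by cosine
#' similarity (descending), ties broken by panel id (ascending).
#'
#' @param query a panel id present in the database.
#' @param db an \linkS4class{EvidenceDB}.
#' @param k number of results (default: the reference K = 400).
#' @return data.frame(panel_id, cosine) with min(k, eligible) rows.
#' @export
retrieveSimilar <- function(query, db, k = 400L) {
  idx <- match(query, db@meta$panel_id)
  if (is.na(idx)) stop("unknown panel id: ", query)
  elig <- db@meta$panel_type == db@meta$panel_type[idx] &
    db@meta$doc_id != db@meta$doc_id[idx]
  if (!any(elig))
    return(data.frame(panel_id = character(0), cosine = numeric(0),
                      stringsAsFactors = FALSE))
  cos <- as.numeric(db@vectors[elig, , drop = FALSE] %*% db@vectors[idx, ])
  ids <- db@meta$panel_id[elig]
  ord <- order(-cos, ids)
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(panel_id = ids[ord], cosine = cos[ord], stringsAsFactors = FALSE)
}

#' Persist / restore an evidence database
#'
#' The on-disk form is a flat binary array of double-precision descriptor
#' values plus a JSON sidecar holding dimensions, panel metadata and the
#' backend name; a save/load round trip reproduces retrieval exactly.
#'
#' @param db an \linkS4class{EvidenceDB}.
#' @param path basename for the store; writes `<path>.bin` and `<path>.json`.
#' @return `saveEvidenceDB` the path, invisibly; `loadEvidenceDB` the
#'   restored \linkS4class{EvidenceDB}.
#' @export
saveEvidenceDB <- function(db, path) {
  writeBin(as.vector(db@vectors), paste0(path, ".bin"), size = 8,
           endian = "little")
  meta <- list(backend = db@backend, nrow = nrow(db@vectors),
               ncol = ncol(db@vectors), panel_id = db@meta$panel_id,
               doc_id = db@meta$doc_id, panel_type = db@meta$panel_type)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname saveEvidenceDB
#' @export
loadEvidenceDB <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$nrow * meta$ncol
  v <- readBin(paste0(path, ".bin"), numeric(), n = n, size = 8,
               endian = "little")
  vecs <- matrix(v, nrow = meta$nrow, ncol = meta$ncol)
  rownames(vecs) <- meta$panel_id
  new("EvidenceDB", vectors = vecs,
      meta = data.frame(panel_id = meta$panel_id, doc_id = meta$doc_id,
                        panel_type = meta$panel_type, stringsAsFactors = FALSE),
      backend = meta$backend)
}
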