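# Minimal PDF support: figure extraction walks the object stream for embedded
# raster XObjects (no page rendering, no layout analysis), and a writer that
# emits one-image-per-page PDFs for fixtures. Supported image encodings:
# uncompressed, FlateDecode and DCTDecode, in DeviceRGB or DeviceGray.

# positions (1-based) where `pattern` (raw) occurs in `x` (raw)
rawFind <- function(x, pattern) {
  p <- charToRaw(pattern)
  hits <- which(x == p[1])
  if (length(p) > 1) {
    for (k in 2:length(p)) {
      hits <- hits[hits + k - 1 <= length(x)]
      hits <- hits[x[hits + k - 1] == p[k]]
    }
  }
  hits
}

# extract embedded raster images from a PDF, in object-stream order
pdfExtractImages <- function(path, minSize = 64L) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (length(bytes) < 5 || rawToChar(bytes[1:5]) != "%PDF-")
    stop("unreadable PDF (missing header): ", path)
  if (length(rawFind(bytes, "/Encrypt")) > 0)
    stop("encrypted PDF not supported: ", path)
  objPos <- rawFind(bytes, " obj")
  images <- list()
  for (pos in objPos) {
    streamPos <- rawFind(bytes[pos:min(pos + 400L, length(bytes))], "stream")
    endPos <- rawFind(bytes[pos:min(pos + 400L, length(bytes))], "endobj")
    dictEnd <- min(c(streamPos, endPos, 400L)) + pos - 1L
    dict <- tryCatch(rawToChar(bytes[pos:dictEnd]), error = function(e) "")
    if (!grepl("/Subtype\\s*/Image", dict)) next
    w <- as.integer(sub(".*?/Width\\s+(\\d+).*", "\\1", dict))
    h <- as.integer(sub(".*?/Height\\s+(\\d+).*", "\\1", dict))
    if (is.na(w) || is.na(h)) next
    gray <- grepl("/DeviceGray", dict)
    filt <- if (grepl("/FlateDecode", dict)) "flate"
            else if (grepl("/DCTDecode", dict)) "dct" else "none"
    # stream payload: after "stream" + EOL, up to "endstream"
    if (length(streamPos) == 0) next
    sStart <- pos + streamPos[1] - 1L + 6L
    while (bytes[sStart] %in% as.raw(c(13L, 10L))) sStart <- sStart + 1L
    endstream <- rawFind(bytes[sStart:length(bytes)], "endstream")
    if (length(endstream) == 0) next
    sEnd <- sStart + endstream[1] - 2L
    while (sEnd > sStart && bytes[sEnd] %in% as.raw(c(13L, 10L))) sEnd <- sEnd - 1L
    payload <- bytes[sStart:sEnd]
    raster <- tryCatch({
      if (filt == "dct") {
        if (!requireNamespace("jpeg", quietly = TRUE))
          stop("jpeg package required for DCTDecode streams")
        asRGB(jpeg::readJPEG(payload))
      } else {
        dat <- if (filt == "flate") memDecompress(payload, type = "gzip")
               else payload
        nchan <- if (gray) 1L else 3L
        if (length(dat) < nchan * w * h) stop("short image stream")
        v <- as.integer(dat[seq_len(nchan * w * h)]) / 255
        if (gray) asRGB(matrix(v, nrow = h, ncol = w, byrow = TRUE))
        else aperm(array(v, dim = c(3L, w, h)), c(3, 2, 1))
      }
    }, error = function(e) NULL)
    if (is.null(raster)) next
    if (min(w, h) < minSize) next
    images[[length(images) + 1L]] <- raster
  }
  images
}

#' Write a fixture PDF with one RGB image per page
#'
#' Emits a minimal PDF whose pages each display one embedded FlateDecode
#' raster; [extractFigures()] round-trips these losslessly (up to 8-bit
#' quantization). Used by the synthetic corpus generator for PDF-input
#' fixtures.
#'
#' @param rasters list of h x w x 3 arrays in [0, 1].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMiniPdf <- function(rasters, path) {
  n <- length(rasters)
  nObj <- 2L + 3L * n
  chunks <- list(charToRaw("%PDF-1.4\n"))
  offsets <- integer(nObj)
  addObj <- function(id, content) {
    offsets[id] <<- sum(vapply(chunks, length, integer(1)))
    chunks[[length(chunks) + 1L]] <<-
      if (is.raw(content)) content else charToRaw(content)
  }
  kids <- paste(sprintf("%d 0 R", 3L + 3L * (seq_len(n) - 1L)), collapse = " ")
  addObj(1L, "1 0 obj << /Type /Catalog /Pages 2 0 R >> endobj\n")
  addObj(2L, sprintf("2 0 obj << /Type /Pages /Kids [%s] /Count %d >> endobj\n",
                     kids, n))
  for (i in seq_len(n)) {
    ras <- clamp01(asRGB(rasters[[i]]))
    h <- dim(ras)[1]; w <- dim(ras)[2]
    pageId <- 3L + 3L * (i - 1L); contId <- pageId + 1L; imgId <- pageId + 2L
    addObj(pageId, sprintf(paste0(
      "%d 0 obj << /Type /Page /Parent 2 0 R /MediaBox [0 0 %d %d] ",
      "/Resources << /XObject << /Im%d %d 0 R >> >> /Contents %d 0 R >> endobj\n"),
      pageId, w, h, i, imgId, contId))
    content <- sprintf("q %d 0 0 %d 0 0 cm /Im%d Do Q", w, h, i)
    addObj(contId, sprintf("%d 0 obj << /Length %d >> stream\n%s\nendstream endobj\n",
                           contId, nchar(content), content))
    pix <- as.raw(round(255 * aperm(ras, c(3, 2, 1))))
    z <- memCompress(as.vector(pix), type = "gzip")
    head <- sprintf(paste0(
      "%d 0 obj << /Type /XObject /Subtype /Image /Width %d /Height %d ",
      "/ColorSpace /DeviceRGB /BitsPerComponent 8 /Filter /FlateDecode ",
      "/Length %d >> stream\n"), imgId, w, h, length(z))
    addObj(imgId, c(charToRaw(head), z, charToRaw("\nendstream endobj\n")))
  }
  xrefAt <- sum(vapply(chunks, length, integer(1)))
  xref <- paste0("xref\n0 ", nObj + 1L, "\n0000000000 65535 f \n",
                 paste(sprintf("%010d 00000 n ", offsets), collapse = "\n"), "\n")
  trailer <- sprintf("trailer << /Size %d /Root 1 0 R >>\nstartxref\n%d\n%%%%EOF\n",
                     nObj + 1L, xrefAt)
  chunks[[length(chunks) + 1L]] <- charToRaw(paste0(xref, trailer))
  con <- file(path, "wb")
  on.exit(close(con))
  for (ch in chunks) writeBin(ch, con)
  invisible(path)
}
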