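# File I/O: grayscale image reading (PNG/PGM/TIFF), text+JSON
# serialization of models and patch sets, and an RF montage writer.

#' Read a grayscale image (PNG, PGM or TIFF)
#'
#' PNG and TIFF are read through the png/tiff packages (16-bit depth
#' honored, values scaled to [0, 1]); RGB(A) inputs are converted to
#' luminance by channel averaging. PGM (P2 ASCII and P5 binary) is
#' parsed directly.
#'
#' @param path file path; format inferred from the extension.
#' @return Numeric matrix (rows x cols) in [0, 1].
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    pgm = readPGM(path),
    stop("readGrayImage: unsupported extension '", ext, "'"))
  if (length(dim(img)) == 3L)
    img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                 c(1, 2), mean)
  img
}

readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("readPGM: not a PGM file")
  # header tokens (width, height, maxval), skipping comments
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1)
    if (length(ch) == 0) stop("readPGM: truncated header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (magic == "P5") {
    sz <- if (maxval > 255) 2L else 1L
    raw <- readBin(con, "integer", n = w * h, size = sz, signed = FALSE,
                   endian = "big")
    m <- matrix(raw, nrow = h, ncol = w, byrow = TRUE)
  } else {
    txt <- readChar(con, file.size(path))
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
    m <- matrix(vals[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
  }
  m / maxval
}

#' Save / load an RBM as flat text plus JSON sidecar
#'
#' The weight matrix and biases are written as whitespace-delimited
#' text at 17 significant digits (lossless for doubles); dimensions and
#' metadata go to a JSON sidecar \code{<path>.json}. Round-trips are
#' bit-exact.
#'
#' @param model an \linkS4class{RBMModel}.
#' @param path base file path for the text payload.
#' @param metadata optional list stored in the sidecar.
#' @return \code{writeRBMModel}: the path, invisibly.
#' @export
writeRBMModel <- function(model, path, metadata = list()) {
  W <- rbmWeights(model)
  # layout: Nv rows of W, then one line b (length Nh), one line c
  nv <- nrow(W); nh <- ncol(W)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(format(W, digits = 17, scientific = TRUE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(paste(format(hiddenBias(model), digits = 17,
                          scientific = TRUE, trim = TRUE),
                   collapse = " "), con)
  writeLines(paste(format(visibleBias(model), digits = 17,
                          scientific = TRUE, trim = TRUE),
                   collapse = " "), con)
  jsonlite::write_json(
    c(list(nVisible = nv, nHidden = nh, format = "divRBM-model-v1"),
      metadata),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRBMModel
#' @return \code{readRBMModel}: the restored \linkS4class{RBMModel}.
#' @export
readRBMModel <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  nv <- meta$nVisible; nh <- meta$nHidden
  lines <- readLines(path)
  parse1 <- function(s) as.numeric(strsplit(trimws(s), " +")[[1]])
  W <- t(vapply(lines[seq_len(nv)], parse1, numeric(nh),
                USE.NAMES = FALSE))
  rbmModel(W = W, b = parse1(lines[nv + 1]), c = parse1(lines[nv + 2]))
}

#' Save / load a PatchSet as flat text plus JSON sidecar
#'
#' @param x a \linkS4class{PatchSet}.
#' @param path base file path.
#' @return \code{writePatchSet}: the path, invisibly;
#'   \code{readPatchSet}: the restored \linkS4class{PatchSet}.
#' @export
writePatchSet <- function(x, path) {
  m <- patchMatrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(format(m, digits = 17, scientific = TRUE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  jsonlite::write_json(
    list(nPatches = nrow(m), patchSide = patchSide(x),
         preprocessing = x@preprocessing,
         provenance = patchProvenance(x),
         format = "divRBM-patches-v1"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePatchSet
#' @export
readPatchSet <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  lines <- readLines(path)
  m <- t(vapply(lines, function(s)
    as.numeric(strsplit(trimws(s), " +")[[1]]),
    numeric(meta$patchSide^2), USE.NAMES = FALSE))
  prov <- as.data.frame(meta$provenance)
  patchSet(m, patchSide = meta$patchSide, provenance = prov,
           preprocessing = as.list(meta$preprocessing))
}

#' Write a tiled PNG montage of receptive fields or basis images
#'
#' Each column of the input matrix is reshaped to a square tile,
#' normalized to [0, 1] (per tile), and laid out on a grid with 1-pixel
#' separators.
#'
#' @param M Nv x Nunits matrix of vectorized fields.
#' @param side tile side length.
#' @param path output PNG path.
#' @param nColumns tiles per row (default: ceiling square).
#' @return The path, invisibly.
#' @export
writeMontage <- function(M, side, path, nColumns = NULL) {
  n <- ncol(M)
  if (is.null(nColumns)) nColumns <- ceiling(sqrt(n))
  nRows <- ceiling(n / nColumns)
  canvas <- matrix(1, nRows * (side + 1) + 1, nColumns * (side + 1) + 1)
  for (j in seq_len(n)) {
    tile <- matrix(M[, j], side, side)
    rng <- range(tile)
    if (diff(rng) > 0) tile <- (tile - rng[1]) / diff(rng)
    else tile <- tile * 0 + 0.5
    r0 <- ((j - 1) %/% nColumns) * (side + 1) + 1
    c0 <- ((j - 1) %% nColumns) * (side + 1) + 1
    canvas[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side)] <- tile
  }
  png::writePNG(canvas, path)
  invisible(path)
}
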