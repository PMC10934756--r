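# Eye-image preprocessing and raster I/O.

# 1-D area-average resampling operator: a (target x source) weight matrix
# whose row i spreads target pixel i over the source pixels it covers, each
# weighted by fractional overlap. Rows sum to 1, so constant images are
# preserved exactly.
areaWeights <- function(nSrc, nTgt) {
  r <- nSrc / nTgt
  W <- matrix(0, nTgt, nSrc)
  for (i in seq_len(nTgt)) {
    lo <- (i - 1) * r
    hi <- i * r
    k0 <- floor(lo) + 1
    k1 <- ceiling(hi)
    for (k in k0:k1) {
      ov <- min(hi, k) - max(lo, k - 1)
      if (ov > 0) W[i, k] <- ov / r
    }
  }
  W
}

#' Preprocess a raw eye image to the 51 x 51 classifier raster
#'
#' Optionally crops to a region of interest, then down-samples to the target
#' size by area averaging (each output pixel is the mean of the source area
#' it covers, which anti-aliases), and rescales intensities to [0, 1] by the
#' image maximum when they exceed that range (e.g. 8-bit 0..255 input);
#' intensities already in [0, 1] pass through unchanged. Upsampling is
#' refused: the source (after cropping) must be at least as large as the
#' target in both dimensions.
#'
#' @param raw numeric intensity matrix (any non-negative scale).
#' @param cropBox optional \code{c(row0, col0, row1, col1)}, 1-based
#'   inclusive bounds within \code{raw}.
#' @param target output size (rows, cols); default \code{c(51, 51)}, giving
#'   the 2601-pixel input the eye-state networks expect.
#' @param label optional class label to attach.
#' @return an \linkS4class{EyeImage}.
#' @export
preprocessImage <- function(raw, cropBox = NULL, target = c(51L, 51L),
                            label = NA_character_) {
  if (!is.matrix(raw) || !length(raw)) stop("raw must be a nonempty matrix")
  stopifnotFinite(raw, "image intensities")
  srcSize <- dim(raw)
  if (!is.null(cropBox)) {
    if (length(cropBox) != 4L ||
        cropBox[1] < 1 || cropBox[2] < 1 ||
        cropBox[3] > nrow(raw) || cropBox[4] > ncol(raw) ||
        cropBox[1] > cropBox[3] || cropBox[2] > cropBox[4])
      stop("cropBox out of raster bounds")
    raw <- raw[cropBox[1]:cropBox[3], cropBox[2]:cropBox[4], drop = FALSE]
  }
  if (nrow(raw) < target[1] || ncol(raw) < target[2])
    stop("refusing to upsample: source smaller than target size")
  out <- areaWeights(nrow(raw), target[1]) %*% raw %*%
    t(areaWeights(ncol(raw), target[2]))
  if (min(out) < 0) out <- out - min(out)
  mx <- max(out)
  if (mx > 1) out <- out / mx
  EyeImage(out, label = label, sourceSize = srcSize)
}

#' Flatten a 51 x 51 raster row by row
#'
#' The image matrix is read row by row into a 2601-element vector: element k
#' (0-based) holds row \code{floor(k / 51)}, column \code{k mod 51}. This is
#' the input-vector convention of the eye-state networks.
#'
#' @param img an \linkS4class{EyeImage} or a raw matrix.
#' @param expectedDim required raster size; pass NULL to flatten any matrix.
#' @return numeric vector of length prod(dim).
#' @export
flattenRowMajor <- function(img, expectedDim = c(51L, 51L)) {
  r <- if (is(img, "EyeImage")) imageRaster(img) else img
  if (!is.matrix(r)) stop("expected a matrix raster")
  if (!is.null(expectedDim) && !all(dim(r) == expectedDim))
    stop(sprintf("raster is %dx%d, expected %dx%d", nrow(r), ncol(r),
                 expectedDim[1], expectedDim[2]))
  as.vector(t(r))
}

#' Read or write grayscale rasters as PGM or PNG
#'
#' PGM files are written in the plain-text P2 variant (maxval 255); P5
#' binary PGM is also read. PNG goes through the \pkg{png} package.
#' Intensities map linearly between [0, 1] and [0, maxval].
#'
#' @param path file path; format chosen by extension (.pgm or .png).
#' @param img an \linkS4class{EyeImage} (for writing).
#' @return \code{readEyeImage}: an \linkS4class{EyeImage} (unlabeled);
#'   \code{writeEyeImage}: the path, invisibly.
#' @export
readEyeImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  r <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- a[, , 1L]
      a
    },
    pgm = readPgm(path),
    stop("unsupported image format: ", ext))
  EyeImage(r, sourceSize = dim(r))
}

#' @rdname readEyeImage
#' @export
writeEyeImage <- function(img, path) {
  r <- imageRaster(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(r, path)
  } else if (ext == "pgm") {
    q <- round(clip01(r) * 255)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(r), nrow(r)), "255"), con)
    write(t(q), con, ncolumns = ncol(r))
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

readPgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # header tokens: width height maxval (comments starting '#' skipped)
  tok <- character(); buf <- ""
  while (length(tok) < 3L) {
    ch <- readChar(con, 1L)
    if (!length(ch)) stop("truncated PGM header")
    if (ch == "#") { repeat { c2 <- readChar(con, 1L)
                              if (!length(c2) || c2 == "\n") break } }
    else if (grepl("[0-9]", ch)) buf <- paste0(buf, ch)
    else if (nzchar(buf)) { tok <- c(tok, buf); buf <- "" }
  }
  dims <- as.integer(tok)
  w <- dims[1]; h <- dims[2]; maxv <- dims[3]
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    scan(con, integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals / maxv, nrow = h, ncol = w, byrow = TRUE)
}
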