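## Image, label and feature-table I/O.
##
## Supported raster formats are 8-bit PNG (via the png package) and the PNM
## family PGM/PPM in both ASCII (P2/P3) and binary (P5/P6) encodings, parsed
## here directly (no installed R package reads PNM). 16-bit images are
## rejected rather than rescaled: the histogram semantics downstream are
## defined over the 8-bit range.

rec601 <- c(0.299, 0.587, 0.114)

## Reduce an h x w x c array (values 0..255) to one channel.
collapseChannels <- function(arr, channelPolicy) {
  if (length(dim(arr)) == 2L) return(arr)
  nc <- dim(arr)[3]
  if (nc == 1L) return(arr[, , 1])
  if (nc == 4L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(arr)[3] != 3L)
    stop("expected 1, 3 or 4 channels, got ", nc)
  out <- switch(channelPolicy,
    green = arr[, , 2],
    luminance = round(rec601[1] * arr[, , 1] + rec601[2] * arr[, , 2] +
                      rec601[3] * arr[, , 3]),
    gray = round((arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3),
    stop("unknown channel policy: ", channelPolicy))
  matrix(out, dim(arr)[1], dim(arr)[2])  # keep matrix shape for 1-pixel edges
}

## ---- PNM (PGM/PPM) ----

pnmNextToken <- function(bytes, pos) {
  n <- length(bytes)
  repeat {
    while (pos <= n && bytes[pos] %in% as.raw(c(9L, 10L, 13L, 32L, 11L, 12L)))
      pos <- pos + 1L
    if (pos <= n && bytes[pos] == as.raw(35L)) {  # '#' comment to end of line
      while (pos <= n && !bytes[pos] %in% as.raw(c(10L, 13L))) pos <- pos + 1L
    } else break
  }
  if (pos > n) stop("unexpected end of PNM header")
  start <- pos
  while (pos <= n && !bytes[pos] %in% as.raw(c(9L, 10L, 13L, 32L, 11L, 12L)))
    pos <- pos + 1L
  list(token = rawToChar(bytes[start:(pos - 1L)]), pos = pos)
}

readPNM <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  tk <- pnmNextToken(bytes, 1L)
  magic <- tk$token
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("not a PGM/PPM file (magic '", magic, "'): ", path)
  tk <- pnmNextToken(bytes, tk$pos); width <- as.integer(tk$token)
  tk <- pnmNextToken(bytes, tk$pos); height <- as.integer(tk$token)
  tk <- pnmNextToken(bytes, tk$pos); maxval <- as.integer(tk$token)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L)
    stop("zero-sized or malformed image: ", path)
  if (is.na(maxval) || maxval < 1L) stop("malformed PNM maxval in ", path)
  if (maxval > 255L)
    stop("16-bit PNM images are not supported (maxval ", maxval, "): ", path)
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  nvals <- width * height * channels
  if (magic %in% c("P5", "P6")) {
    datapos <- tk$pos + 1L  # exactly one whitespace byte after maxval
    if (datapos + nvals - 1L > length(bytes))
      stop("truncated PNM pixel data in ", path)
    vals <- as.integer(bytes[datapos:(datapos + nvals - 1L)])
  } else {
    txt <- rawToChar(bytes[tk$pos:length(bytes)])
    vals <- suppressWarnings(as.integer(strsplit(trimws(txt), "[ \t\r\n\v\f]+")[[1]]))
    if (length(vals) < nvals || anyNA(vals))
      stop("truncated or malformed ASCII PNM pixel data in ", path)
    vals <- vals[seq_len(nvals)]
  }
  if (any(vals > maxval)) stop("PNM pixel value exceeds maxval in ", path)
  if (channels == 1L) {
    matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  } else {
    ## interleaved RGB, row-major
    arr <- array(0L, c(height, width, 3L))
    m <- matrix(vals, ncol = 3L, byrow = TRUE)
    for (c in 1:3)
      arr[, , c] <- matrix(m[, c], nrow = height, ncol = width, byrow = TRUE)
    arr
  }
}

## ---- public API ----

#' Read a fundus image
#'
#' Reads an 8-bit PNG, PGM or PPM image and reduces colour inputs to the
#' single intensity channel the pipeline operates on. The default policy keeps
#' the green channel, where exudates and vessels show the highest contrast in
#' fundus photography; `"luminance"` applies the Rec.601 weights
#' (0.299, 0.587, 0.114) rounded to the nearest integer, and `"gray"`
#' averages the three channels. Single-channel inputs ignore the policy.
#' 16-bit inputs are rejected.
#'
#' @param path path to a `.png`, `.pgm` or `.ppm` file.
#' @param channelPolicy one of `"green"`, `"luminance"`, `"gray"`.
#' @param sourceId identifier stored on the image; defaults to the file name
#'   without extension.
#' @return a [FundusImage-class].
#' @examples
#' p <- tempfile(fileext = ".pgm")
#' writeFundusImage(FundusImage(matrix(200L, 4, 4), "demo"), p)
#' readFundusImage(p)
#' @export
readFundusImage <- function(path, channelPolicy = c("green", "luminance", "gray"),
                            sourceId = NULL) {
  channelPolicy <- match.arg(channelPolicy)
  if (!file.exists(path)) stop("cannot read image file: ", path)
  if (is.null(sourceId)) sourceId <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    arr <- png::readPNG(path) * 255
    if (max(abs(arr - round(arr))) > 1e-6)
      stop("only 8-bit PNG images are supported: ", path)
    arr <- round(arr)
  } else if (ext %in% c("pgm", "ppm", "pnm")) {
    arr <- readPNM(path)
  } else {
    stop("unsupported image format '", ext, "': ", path)
  }
  if (any(dim(arr)[1:2] < 1L)) stop("zero-sized image: ", path)
  FundusImage(collapseChannels(arr, channelPolicy), sourceId)
}

#' Write a fundus image
#'
#' Writes a [FundusImage-class] to disk as binary PGM (`.pgm`) or 8-bit
#' grayscale PNG (`.png`). Both round-trip losslessly through
#' [readFundusImage()].
#'
#' @param image a [FundusImage-class].
#' @param path destination path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
writeFundusImage <- function(image, path) {
  stopifnot(is(image, "FundusImage"))
  p <- pixels(image)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "pgm") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(p), nrow(p)), con, eos = NULL)
    writeBin(as.raw(as.vector(t(p))), con)
  } else if (ext == "png") {
    png::writePNG(p / 255, path)
  } else {
    stop("unsupported output format '", ext, "': ", path)
  }
  invisible(path)
}

#' Read an image-label table
#'
#' Reads the CSV label schema `source_id,diseased,severity_grade` and checks
#' the dataset invariants: flags in \{0, 1\}, grades in \[0, maxGrade\], and
#' grade 0 exactly for non-diseased rows.
#'
#' @param path CSV file path.
#' @param maxGrade maximum admissible severity grade.
#' @return a data.frame with the three validated columns.
#' @export
readLabels <- function(path, maxGrade = 4L) {
  if (!file.exists(path)) stop("cannot read labels file: ", path)
  lab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_id", "diseased", "severity_grade")
  miss <- setdiff(need, names(lab))
  if (length(miss))
    stop("labels file is missing column(s): ", paste(miss, collapse = ", "))
  lab <- lab[need]
  if (!all(lab$diseased %in% c(0L, 1L)))
    stop("diseased flags must be 0 or 1")
  bad <- which(lab$severity_grade < 0 | lab$severity_grade > maxGrade)
  if (length(bad))
    stop("severity grade out of range [0, ", maxGrade, "] in row(s): ",
         paste(bad, collapse = ", "))
  bad <- which((lab$severity_grade == 0) != (lab$diseased == 0))
  if (length(bad))
    stop("severity_grade must be 0 exactly when diseased is 0; violated in row(s): ",
         paste(bad, collapse = ", "))
  lab$diseased <- as.integer(lab$diseased)
  lab$severity_grade <- as.integer(lab$severity_grade)
  lab
}

#' Write and read per-image feature tables
#'
#' One row per image: `source_id`, the per-block group-sparsity values
#' `gs_1..gs_k` in row-major block order, and `extraction_time_ms`. Values
#' survive the round trip to at least 12 significant digits.
#'
#' @param features a list of [ImageFeatures-class] objects (all from the same
#'   window configuration).
#' @param path CSV destination / source.
#' @return `writeFeatures` returns `path` invisibly; `readFeatures` returns a
#'   data.frame.
#' @export
writeFeatures <- function(features, path) {
  if (length(features) == 0L) {
    writeLines("source_id,extraction_time_ms", path)
    return(invisible(path))
  }
  k <- length(gsValues(features[[1]]))
  rows <- lapply(features, function(f) {
    stopifnot(length(gsValues(f)) == k)
    data.frame(source_id = sourceId(f),
               t(stats::setNames(gsValues(f), paste0("gs_", seq_len(k)))),
               extraction_time_ms = extractionTime(f),
               check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  if (!file.exists(path)) stop("cannot read features file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
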