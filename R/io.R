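#' Read a reference spectrum from a two-column table
#'
#' Parses a CSV or TSV of (wavenumber cm^-1, intensity). A header line is
#' tolerated; every remaining row must yield two numbers. Rows are sorted to
#' an ascending axis; duplicate wavenumbers are rejected.
#'
#' @param path File path.
#' @param dialect `"csv_2col"` or `"tsv_2col"`; the default guesses from the
#'   file extension (`.tsv`/`.txt` are tab-separated, everything else comma).
#' @return A raw-stage `raman_spectrum` labelled with the file's base name.
#' @export
read_reference <- function(path, dialect = c("auto", "csv_2col", "tsv_2col")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
      "tsv_2col" else "csv_2col"
  }
  sep <- if (dialect == "tsv_2col") "\t" else ","
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  start <- 1L
  first <- strsplit(trimws(lines[1]), sep, fixed = TRUE)[[1]]
  if (length(first) >= 2 &&
      any(is.na(suppressWarnings(as.numeric(first[1:2]))))) {
    start <- 2L  # header row
  }
  if (length(lines) < start + 1L) {
    stop("a spectrum needs at least 2 data rows: ", path, call. = FALSE)
  }
  n <- length(lines) - start + 1L
  wn <- numeric(n)
  it <- numeric(n)
  for (k in seq_len(n)) {
    ln <- start + k - 1L
    parts <- strsplit(trimws(lines[ln]), sep, fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2 || any(is.na(vals[1:2]))) {
      stop(sprintf("malformed row at line %d of %s: '%s'", ln, path, lines[ln]),
           call. = FALSE)
    }
    wn[k] <- vals[1]
    it[k] <- vals[2]
  }
  if (anyDuplicated(wn)) {
    stop(sprintf("duplicated wavenumber(s) in %s: %s", path,
                 paste(unique(wn[duplicated(wn)]), collapse = ", ")),
         call. = FALSE)
  }
  ord <- order(wn)
  raman_spectrum(wn[ord], it[ord], stage = "raw",
                 label = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a reference spectrum as a two-column table
#'
#' @param s A `raman_spectrum`.
#' @param path Output path.
#' @param dialect `"csv_2col"` or `"tsv_2col"`.
#' @return The path, invisibly.
#' @export
write_reference <- function(s, path, dialect = c("csv_2col", "tsv_2col")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv_2col") "\t" else ","
  df <- data.frame(wavenumber_cm1 = s$wavenumber, intensity = s$intensity)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_axis_sidecar <- function(axis_path) {
  if (grepl("\\.json$", axis_path, ignore.case = TRUE)) {
    j <- jsonlite::fromJSON(axis_path)
    if (is.list(j) && !is.null(j$wavenumber)) {
      list(wavenumber = as.numeric(j$wavenumber),
           intensity_scale = if (!is.null(j$intensity_scale))
             as.numeric(j$intensity_scale) else 1)
    } else {
      list(wavenumber = as.numeric(j), intensity_scale = 1)
    }
  } else {
    v <- utils::read.csv(axis_path, header = FALSE,
                         colClasses = "character")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num[1])) num <- num[-1]  # header line
    if (anyNA(num)) stop("non-numeric entries in axis sidecar", call. = FALSE)
    list(wavenumber = num, intensity_scale = 1)
  }
}

#' Read a hyperspectral stack from a multi-page TIFF
#'
#' The image volume is band-sequential (one TIFF page per band); the
#' wavenumber of each band comes from a sidecar file, either a one-column
#' CSV or a JSON object `{"wavenumber": [...], "intensity_scale": s}`.
#' TIFF samples are normalized to \[0, 1\] on read (the TIFF convention for
#' integer data) and multiplied by `intensity_scale` to restore native
#' units; a descending sidecar axis causes the bands to be reversed so the
#' in-memory axis is always ascending.
#'
#' @param image_path Multi-page TIFF path.
#' @param axis_path Sidecar path (CSV or JSON).
#' @return An `hsi_stack`.
#' @export
read_stack <- function(image_path, axis_path) {
  pages <- tiff::readTIFF(image_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  ax <- read_axis_sidecar(axis_path)
  wn <- ax$wavenumber
  if (length(pages) != length(wn)) {
    stop(sprintf("page count (%d) does not match axis length (%d)",
                 length(pages), length(wn)), call. = FALSE)
  }
  if (all(diff(wn) < 0)) {  # descending sidecar: flip to ascending
    wn <- rev(wn)
    pages <- rev(pages)
  }
  if (any(diff(wn) <= 0)) {
    stop("band axis is not monotone after sorting", call. = FALSE)
  }
  d <- dim(pages[[1]])
  data <- array(0, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) data[, , k] <- pages[[k]] * ax$intensity_scale
  hsi_stack(data, wn, meta = list(source = image_path))
}

#' Write a hyperspectral stack as multi-page TIFF + JSON sidecar
#'
#' Intensities are scaled by their maximum into \[0, 1\] and written as
#' 32-bit samples; the scale factor is stored in the JSON sidecar so
#' [read_stack()] restores native units (round trip well within float32
#' precision).
#'
#' @param stack An `hsi_stack`.
#' @param image_path Output TIFF path.
#' @param axis_path Output JSON sidecar path.
#' @return `image_path`, invisibly.
#' @export
write_stack <- function(stack, image_path, axis_path) {
  stopifnot(inherits(stack, "hsi_stack"))
  if (min(stack$data) < 0) {
    stop("write_stack supports nonnegative intensities only", call. = FALSE)
  }
  scale <- max(stack$data)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(stack$data)[3]),
                  function(k) stack$data[, , k] / scale)
  tiff::writeTIFF(pages, image_path, bits.per.sample = 32L)
  jsonlite::write_json(list(wavenumber = stack$wavenumber,
                            intensity_scale = scale),
                       axis_path, digits = NA, auto_unbox = TRUE)
  invisible(image_path)
}

#' Write a score image to TIFF
#'
#' `float32` writes the raw scores as a single-page high-depth TIFF;
#' `uint8_fixed` maps scores by the fixed transform `round(score * 255)` —
#' not a per-image stretch — so 8-bit score images remain directly
#' comparable across references and stacks. Masked pixels are written as 0;
#' the mask itself can be saved with [write_mask()].
#'
#' @param img A `score_image`.
#' @param path Output TIFF path.
#' @param mode `"float32"` or `"uint8_fixed"`.
#' @return The path, invisibly.
#' @export
write_score_image <- function(img, path, mode = c("float32", "uint8_fixed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "score_image"))
  s <- img$scores
  s[img$mask] <- 0
  if (any(!is.finite(s))) stop("scores must be finite or masked", call. = FALSE)
  if (mode == "uint8_fixed") {
    # quantize here with round-half-even, then bias by half a level so the
    # writer's truncation lands exactly on round(score * 255)
    q <- round(s * 255)
    tiff::writeTIFF(pmin((q + 0.5) / 255, 1), path, bits.per.sample = 8L)
  } else {
    tiff::writeTIFF(s, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a score image written by [write_score_image()]
#'
#' @param path TIFF path.
#' @return A numeric matrix of scores in `[0, 1]`.
#' @export
read_score_matrix <- function(path) {
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  p
}

#' Write / read a binary mask as uint8 TIFF (0/255)
#'
#' @param mask Logical matrix.
#' @param path TIFF path.
#' @return `write_mask`: the path, invisibly. `read_mask`: a logical matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  p > 0.5
}
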