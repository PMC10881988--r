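#' Construct a Raman spectrum
#'
#' A spectrum is a single spectral trace: a strictly increasing wavenumber
#' axis (cm^-1) with one intensity per point, tagged with the preprocessing
#' stage it has reached.
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, strictly
#'   increasing, length >= 2.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `wavenumber`.
#' @param stage Preprocessing stage, one of `"raw"`, `"baseline_corrected"`,
#'   `"minmax"`, `"unit_norm"`.
#' @param label Free-text label (e.g. the compound name).
#' @param coverage Optional logical vector marking grid points backed by
#'   measured data (`FALSE` = zero-filled outside the original axis range).
#'   Defaults to all `TRUE`.
#' @return An object of class `raman_spectrum`.
#' @examples
#' s <- raman_spectrum(c(2850, 2935), c(1, 0.5), label = "demo")
#' @export
raman_spectrum <- function(wavenumber, intensity,
                           stage = c("raw", "baseline_corrected", "minmax", "unit_norm"),
                           label = "", coverage = NULL) {
  stage <- match.arg(stage)
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("wavenumber and intensity must have the same length", call. = FALSE)
  }
  if (length(wavenumber) < 2L) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (anyNA(wavenumber) || anyNA(intensity) ||
      any(!is.finite(wavenumber)) || any(!is.finite(intensity))) {
    stop("spectrum contains non-finite values", call. = FALSE)
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  }
  if (is.null(coverage)) coverage <- rep(TRUE, length(wavenumber))
  stopifnot(is.logical(coverage), length(coverage) == length(wavenumber))
  s <- structure(
    list(wavenumber = wavenumber, intensity = intensity,
         stage = stage, label = label, coverage = coverage),
    class = "raman_spectrum"
  )
  validate_spectrum(s)
  s
}

validate_spectrum <- function(s) {
  if (s$stage == "minmax") {
    if (abs(min(s$intensity)) > 1e-9 || abs(max(s$intensity) - 1) > 1e-9) {
      stop("minmax-stage spectrum must have min 0 and max 1", call. = FALSE)
    }
  }
  if (s$stage == "unit_norm") {
    if (abs(sqrt(sum(s$intensity^2)) - 1) >= 1e-9) {
      stop("unit_norm-stage spectrum must have Euclidean norm 1", call. = FALSE)
    }
  }
  invisible(s)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d points, %.1f-%.1f cm-1, stage: %s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber), x$stage))
  if (!all(x$coverage)) {
    cat(sprintf("  %d grid points outside measured coverage (zero-filled)\n",
                sum(!x$coverage)))
  }
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

#' Construct a reference library
#'
#' An ordered, named collection of reference spectra preprocessed to the
#' `unit_norm` stage on one shared interpolation grid, ready for matching
#' against pixel spectra.
#'
#' @param spectra Named list of `raman_spectrum` objects at stage
#'   `"unit_norm"`, all sharing an identical wavenumber axis.
#' @return An object of class `reference_library` with elements `entries`
#'   (the named list) and `grid` (the shared axis).
#' @export
reference_library <- function(spectra) {
  if (!is.list(spectra)) {
    stop("spectra must be a named list", call. = FALSE)
  }
  if (length(spectra) == 0) {
    return(structure(list(entries = list(), grid = numeric(0)),
                     class = "reference_library"))
  }
  nm <- names(spectra)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("reference names must be unique and non-empty", call. = FALSE)
  }
  for (s in spectra) {
    if (!inherits(s, "raman_spectrum")) {
      stop("all entries must be raman_spectrum objects", call. = FALSE)
    }
    if (s$stage != "unit_norm") {
      stop("library entries must be at stage 'unit_norm'", call. = FALSE)
    }
  }
  grid <- spectra[[1]]$wavenumber
  for (s in spectra) {
    if (length(s$wavenumber) != length(grid) || any(s$wavenumber != grid)) {
      stop("all library entries must share an identical axis", call. = FALSE)
    }
  }
  structure(list(entries = spectra, grid = grid), class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  if (length(x$entries) == 0) {
    cat("<reference_library> empty\n")
    return(invisible(x))
  }
  cat(sprintf("<reference_library> %d entries on %d-point grid (%.0f-%.0f cm-1)\n",
              length(x$entries), length(x$grid), min(x$grid), max(x$grid)))
  cat(" ", paste(names(x$entries), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.reference_library <- function(x) length(x$entries)

#' Construct a hyperspectral stack
#'
#' A rows x cols x bands intensity volume with a single shared wavenumber
#' axis: every pixel holds one intensity per acquired Raman shift.
#'
#' @param data Numeric array of dimension rows x cols x bands, finite values.
#' @param wavenumber Band wavenumbers in cm^-1, strictly increasing, length
#'   equal to the number of bands.
#' @param meta Optional list of acquisition notes.
#' @return An object of class `hsi_stack`.
#' @export
hsi_stack <- function(data, wavenumber, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a rows x cols x bands array", call. = FALSE)
  }
  if (any(dim(data)[1:2] < 1L)) stop("stack must have rows, cols >= 1", call. = FALSE)
  wavenumber <- as.numeric(wavenumber)
  if (dim(data)[3] != length(wavenumber)) {
    stop(sprintf("band count (%d) does not match axis length (%d)",
                 dim(data)[3], length(wavenumber)), call. = FALSE)
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("band axis must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("stack intensities must be finite", call. = FALSE)
  structure(list(data = data, wavenumber = wavenumber, meta = meta),
            class = "hsi_stack")
}

#' @export
print.hsi_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_stack> %d x %d pixels, %d bands (%.0f-%.0f cm-1)\n",
              d[1], d[2], d[3], min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' @export
dim.hsi_stack <- function(x) dim(x$data)

#' Construct a score image
#'
#' Per-pixel similarity scores of one hyperspectral stack against one
#' reference spectrum, with the best spectral shift found per pixel and a
#' mask of degenerate pixels (constant or empty spectra that cannot be
#' normalized).
#'
#' @param scores Numeric matrix of similarity scores in `[0, 1]`
#'   (masked pixels hold 0).
#' @param best_shift Numeric matrix of the best spectral offset per pixel,
#'   signed cm^-1 (positive = reference moved toward higher wavenumber).
#' @param mask Logical matrix, `TRUE` where the pixel is degenerate/masked.
#' @param reference_name Name of the reference the scores refer to.
#' @param config The `prm_config` used (snapshot).
#' @return An object of class `score_image`.
#' @export
score_image <- function(scores, best_shift, mask = NULL,
                        reference_name = "", config = NULL) {
  stopifnot(is.matrix(scores), is.matrix(best_shift),
            all(dim(scores) == dim(best_shift)))
  if (is.null(mask)) mask <- matrix(FALSE, nrow(scores), ncol(scores))
  stopifnot(is.matrix(mask), all(dim(mask) == dim(scores)))
  ok <- !mask
  if (any(scores[ok] < 0 | scores[ok] > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(config) && any(abs(best_shift[ok]) > config$max_shift + 1e-9)) {
    stop("|best_shift| exceeds configured max_shift", call. = FALSE)
  }
  structure(list(scores = scores, best_shift = best_shift, mask = mask,
                 reference_name = reference_name, config = config),
            class = "score_image")
}

#' @export
print.score_image <- function(x, ...) {
  ok <- !x$mask
  cat(sprintf("<score_image> vs '%s': %d x %d, scores %.4f-%.4f (%d masked)\n",
              x$reference_name, nrow(x$scores), ncol(x$scores),
              if (any(ok)) min(x$scores[ok]) else NA_real_,
              if (any(ok)) max(x$scores[ok]) else NA_real_,
              sum(x$mask)))
  invisible(x)
}

#' @export
dim.score_image <- function(x) dim(x$scores)
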