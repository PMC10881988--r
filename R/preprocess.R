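#' Preprocessing configuration
#'
#' Bundles the common-grid interpolation settings and the baseline-correction
#' choice applied identically to pixel spectra and reference spectra, so the
#' two stay comparable under the inner product.
#'
#' @param grid_step Interpolation step in cm^-1 (default 1, i.e. every
#'   integer wavenumber).
#' @param grid_range Two-element `c(lo, hi)` in cm^-1; default
#'   `c(2700, 3150)`, the CH-stretching region.
#' @param baseline One of `"none"`, `"subtract_measured"` (subtract a
#'   supplied background spectrum), `"arpls"` (asymmetrically reweighted
#'   penalized least squares estimate).
#' @param arpls_lambda Smoothness weight of the Whittaker smoother
#'   (default 1e5).
#' @param arpls_ratio Termination threshold on the relative weight change
#'   (default 1e-6).
#' @param arpls_max_iter Iteration cap (default 50).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(grid_step = 1, grid_range = c(2700, 3150),
                              baseline = c("none", "subtract_measured", "arpls"),
                              arpls_lambda = 1e5, arpls_ratio = 1e-6,
                              arpls_max_iter = 50L) {
  baseline <- match.arg(baseline)
  stopifnot(grid_step > 0, length(grid_range) == 2,
            grid_range[1] < grid_range[2],
            arpls_lambda > 0, arpls_ratio > 0, arpls_max_iter >= 1)
  structure(list(grid_step = grid_step, grid_range = as.numeric(grid_range),
                 baseline = baseline, arpls_lambda = arpls_lambda,
                 arpls_ratio = arpls_ratio,
                 arpls_max_iter = as.integer(arpls_max_iter)),
            class = "preprocess_config")
}

grid_axis <- function(cfg) {
  seq(cfg$grid_range[1], cfg$grid_range[2], by = cfg$grid_step)
}

degenerate_error <- function(msg) {
  stop(structure(class = c("degenerate_spectrum", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Interpolate a spectrum onto the common grid
#'
#' Linear interpolation at every grid point covered by the spectrum's axis;
#' grid points outside the measured range are zero-filled and flagged in
#' `coverage` so they can propagate into the score mask.
#'
#' @param s A `raman_spectrum`.
#' @param cfg A `preprocess_config`.
#' @return A `raman_spectrum` on the grid axis, same stage as the input.
#' @export
interpolate_to_grid <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "raman_spectrum"), inherits(cfg, "preprocess_config"))
  grid <- grid_axis(cfg)
  inside <- grid >= min(s$wavenumber) & grid <= max(s$wavenumber)
  if (!any(inside)) {
    stop(sprintf("spectrum (%.0f-%.0f cm-1) does not overlap grid range (%.0f-%.0f cm-1)",
                 min(s$wavenumber), max(s$wavenumber),
                 cfg$grid_range[1], cfg$grid_range[2]), call. = FALSE)
  }
  out <- numeric(length(grid))
  out[inside] <- stats::approx(s$wavenumber, s$intensity,
                               xout = grid[inside], method = "linear")$y
  raman_spectrum(grid, out, stage = s$stage, label = s$label,
                 coverage = inside)
}

#' Min-max normalize a spectrum
#'
#' Rescales intensities to `(I - Imin) / (Imax - Imin)` so the spectrum spans
#' exactly \[0, 1\]: matching then depends on spectral shape only, not on
#' overall intensity.
#'
#' @param s A `raman_spectrum`.
#' @return A `raman_spectrum` at stage `"minmax"`.
#'   A constant spectrum raises a condition of class `degenerate_spectrum`;
#'   the pixel-scoring path converts this to a masked zero score, while the
#'   reference path lets it propagate as an error.
#' @export
minmax_normalize <- function(s) {
  stopifnot(inherits(s, "raman_spectrum"))
  lo <- min(s$intensity)
  hi <- max(s$intensity)
  if (hi <= lo) degenerate_error("constant spectrum: Imax == Imin")
  raman_spectrum(s$wavenumber, (s$intensity - lo) / (hi - lo),
                 stage = "minmax", label = s$label, coverage = s$coverage)
}

#' Euclidean (unit-norm) normalize a spectrum
#'
#' Divides the intensities by their Euclidean norm so the inner product of
#' two spectra is their cosine similarity.
#'
#' @param s A `raman_spectrum`.
#' @return A `raman_spectrum` at stage `"unit_norm"`. A zero spectrum raises
#'   a `degenerate_spectrum` condition.
#' @export
unit_normalize <- function(s) {
  stopifnot(inherits(s, "raman_spectrum"))
  nrm <- sqrt(sum(s$intensity^2))
  if (nrm <= 0) degenerate_error("zero spectrum: Euclidean norm is 0")
  raman_spectrum(s$wavenumber, s$intensity / nrm,
                 stage = "unit_norm", label = s$label, coverage = s$coverage)
}

#' arPLS baseline correction
#'
#' Estimates a slowly varying baseline by asymmetrically reweighted penalized
#' least squares: iterated weighted Whittaker smoothing where points above
#' the current baseline (peaks) are logistically down-weighted, until the
#' relative change in the weight vector falls below `arpls_ratio` or
#' `arpls_max_iter` is reached. Returns the spectrum minus the estimated
#' baseline.
#'
#' @param s A `raman_spectrum` with at least 10 points.
#' @param cfg A `preprocess_config` supplying `arpls_lambda`, `arpls_ratio`,
#'   `arpls_max_iter`.
#' @return A `raman_spectrum` at stage `"baseline_corrected"`. If the
#'   iteration hits `arpls_max_iter` without meeting the ratio a warning is
#'   emitted and the best estimate returned.
#' @references Baek, S.-J. et al. (2015) Baseline correction using
#'   asymmetrically reweighted penalized least squares smoothing.
#'   Analyst 140, 250-257.
#' @export
arpls_baseline <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "raman_spectrum"), inherits(cfg, "preprocess_config"))
  y <- s$intensity
  n <- length(y)
  if (n < 10L) stop("arPLS needs at least 10 points", call. = FALSE)
  z <- arpls_fit(y, cfg$arpls_lambda, cfg$arpls_ratio, cfg$arpls_max_iter)
  raman_spectrum(s$wavenumber, y - z, stage = "baseline_corrected",
                 label = s$label, coverage = s$coverage)
}

# core arPLS iteration on a plain numeric vector; returns the baseline z
arpls_fit <- function(y, lambda, ratio, max_iter) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2L, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L), rep(1, n - 2L)))
  H <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + H, w * y))
    d <- y - z
    dn <- d[d < 0]
    if (length(dn) < 2L) break  # baseline already below all points
    # on noiseless signals the negative residuals shrink to numerical noise
    # and the logistic weights chatter; treat that as converged
    if (max(-dn) < 1e-9 * max(diff(range(y)), 1e-300)) break
    m <- mean(dn)
    sdev <- stats::sd(dn)
    if (!is.finite(sdev) || sdev == 0) break
    wt <- 1 / (1 + exp(2 * (d - (2 * sdev - m)) / sdev))
    if (sqrt(sum((w - wt)^2)) / sqrt(sum(w^2)) < ratio) {
      w <- wt
      break
    }
    w <- wt
    if (it == max_iter) {
      warning("arPLS did not converge within arpls_max_iter; returning best estimate",
              call. = FALSE)
    }
  }
  z
}

#' Full pixel/reference preprocessing chain
#'
#' Applies, in order: baseline correction (per `cfg$baseline`), linear
#' interpolation onto the common grid, min-max normalization, and Euclidean
#' normalization. The identical chain is used for pixel spectra and for
#' reference spectra, which is what makes their inner product meaningful.
#'
#' @param raw A `raman_spectrum` (any stage; typically raw).
#' @param cfg A `preprocess_config`.
#' @param background Optional `raman_spectrum` measured background, required
#'   when `cfg$baseline == "subtract_measured"`; it must share the raw axis.
#' @return A `raman_spectrum` at stage `"unit_norm"` on the grid axis.
#'   Degenerate inputs (constant or zero after the chain) raise a
#'   `degenerate_spectrum` condition.
#' @export
preprocess_pixel <- function(raw, cfg = preprocess_config(), background = NULL) {
  stopifnot(inherits(raw, "raman_spectrum"), inherits(cfg, "preprocess_config"))
  s <- switch(cfg$baseline,
    none = raw,
    subtract_measured = {
      if (is.null(background)) {
        stop("baseline 'subtract_measured' requires a background spectrum", call. = FALSE)
      }
      stopifnot(length(background$wavenumber) == length(raw$wavenumber),
                all(background$wavenumber == raw$wavenumber))
      raman_spectrum(raw$wavenumber, raw$intensity - background$intensity,
                     stage = "baseline_corrected", label = raw$label,
                     coverage = raw$coverage)
    },
    arpls = arpls_baseline(raw, cfg)
  )
  unit_normalize(minmax_normalize(interpolate_to_grid(s, cfg)))
}

#' Preprocess a raw reference spectrum for the library
#'
#' Same chain as [preprocess_pixel()]; kept as a named entry point because a
#' degenerate reference is a hard error (there is no pixel mask to absorb it).
#'
#' @inheritParams preprocess_pixel
#' @return A `raman_spectrum` at stage `"unit_norm"`.
#' @export
preprocess_reference <- function(raw, cfg = preprocess_config(), background = NULL) {
  preprocess_pixel(raw, cfg, background)
}

#' Build a reference library from raw spectra
#'
#' Preprocesses each raw reference through the full chain and assembles the
#' result into a [reference_library()] on the shared grid.
#'
#' @param raw_spectra Named list of raw `raman_spectrum` objects.
#' @param cfg A `preprocess_config`.
#' @return A `reference_library`.
#' @export
build_library <- function(raw_spectra, cfg = preprocess_config()) {
  entries <- lapply(raw_spectra, preprocess_reference, cfg = cfg)
  reference_library(entries)
}
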