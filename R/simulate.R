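# run code under a fixed RNG state without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation settings for synthetic stacks
#'
#' Describes a synthetic hyperspectral acquisition: spectra are built on a
#' fine 1 cm^-1 grid, per-pixel mixtures are brightness-scaled, spectrally
#' jittered and noised, then resampled to the coarser acquired band axis
#' (default 75 bands at 6 cm^-1 spacing across the CH-stretching window,
#' matching a typical SRS hyperspectral scan).
#'
#' @param seed Integer RNG seed; all outputs are pure functions of the
#'   settings and this seed.
#' @param grid_range,grid_step Fine simulation grid (default 2700-3150 at
#'   1 cm^-1).
#' @param n_bands Number of acquired bands (default 75).
#' @param band_step Acquired band spacing in cm^-1 (default 6).
#' @param noise_sd Additive Gaussian noise s.d. on raw intensities
#'   (default 0.01, i.e. ~1% of a unit-height peak).
#' @param jitter_sd Per-pixel spectral shift s.d. in cm^-1 (default 3).
#' @param layout Spatial layout of the ground-truth composition:
#'   `"two_phase"` (left/right halves), `"droplets"` (discs of the second
#'   component on a background of the first), `"fraction_ramp"` (the first
#'   component's weight ramps 0 to 1 across columns).
#' @param nrow,ncol Image size in pixels (default 16 x 16).
#' @param brightness_range Per-pixel multiplicative brightness factor range,
#'   drawn uniformly (default 0.5-2), so fixtures exercise the claim that
#'   spectral shape, not intensity, drives the score.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(seed = 0L, grid_range = c(2700, 3150), grid_step = 1,
                     n_bands = 75L, band_step = 6,
                     noise_sd = 0.01, jitter_sd = 3,
                     layout = c("two_phase", "droplets", "fraction_ramp"),
                     nrow = 16L, ncol = 16L,
                     brightness_range = c(0.5, 2)) {
  layout <- match.arg(layout)
  stopifnot(noise_sd >= 0, jitter_sd >= 0, nrow >= 1, ncol >= 1,
            n_bands >= 2, band_step > 0,
            grid_range[1] + (n_bands - 1) * band_step <= grid_range[2])
  structure(list(seed = as.integer(seed), grid_range = as.numeric(grid_range),
                 grid_step = grid_step, n_bands = as.integer(n_bands),
                 band_step = band_step, noise_sd = noise_sd,
                 jitter_sd = jitter_sd, layout = layout,
                 nrow = as.integer(nrow), ncol = as.integer(ncol),
                 brightness_range = as.numeric(brightness_range)),
            class = "sim_spec")
}

#' Build a sum-of-Gaussians reference spectrum
#'
#' @param peaks List of `c(amplitude, center, width)` triplets, centers in
#'   cm^-1 within the grid.
#' @param grid Wavenumber axis (default the 1 cm^-1 CH-region grid
#'   2700-3150).
#' @param label Spectrum label.
#' @return A raw-stage `raman_spectrum`.
#' @examples
#' s <- make_reference(list(c(1, 2850, 14), c(0.5, 2935, 20)), label = "demo")
#' @export
make_reference <- function(peaks, grid = seq(2700, 3150, by = 1), label = "") {
  if (!is.list(peaks) || length(peaks) == 0) {
    stop("peaks must be a non-empty list of (amplitude, center, width)", call. = FALSE)
  }
  y <- numeric(length(grid))
  for (p in peaks) {
    stopifnot(length(p) == 3, p[3] > 0)
    if (p[2] < min(grid) || p[2] > max(grid)) {
      stop("peak center outside the grid", call. = FALSE)
    }
    y <- y + p[1] * exp(-(grid - p[2])^2 / (2 * p[3]^2))
  }
  raman_spectrum(grid, y, stage = "raw", label = label)
}

#' Peak sets for three synthetic lipid-like references
#'
#' Gaussian peak lists on the canonical CH-stretching bands, with amplitude
#' ratios chosen so the three spectra are clearly discriminable after
#' normalization: `tag_like` is CH2-dominant (2850 cm^-1, as in
#' triacylglycerol-rich droplets), `pe_like` is CH3-dominant (2935 cm^-1,
#' with an olefinic 3065 cm^-1 shoulder), `chol_like` is 2880-dominant
#' (sterol ring CH). These are synthetic stand-ins for pure-standard
#' spectra, not measured references.
#'
#' @return Named list of peak lists, each usable with [make_reference()].
#' @export
demo_peak_sets <- function() {
  list(
    tag_like = list(c(1.00, 2850, 14), c(0.60, 2880, 16),
                    c(0.45, 2935, 22), c(0.10, 3010, 18)),
    pe_like = list(c(0.55, 2850, 14), c(0.45, 2880, 16),
                   c(1.00, 2935, 22), c(0.30, 3065, 30)),
    chol_like = list(c(0.70, 2850, 14), c(1.00, 2880, 14),
                     c(0.50, 2935, 20), c(0.20, 3065, 25))
  )
}

#' Shift-confusable reference pair for penalty-regime evaluation
#'
#' A two-phase fixture pair built so the penalty coefficient has an interior
#' optimum, the regime the score is designed around. `phase_a` is a narrow
#' two-band spectrum (2850/2935 cm^-1). `phase_b`'s dominant band (2760
#' cm^-1) sits farther from any `phase_a` band than the shift search ever
#' reaches, but it carries a weak satellite 20 cm^-1 above `phase_a`'s main
#' band — the wrong-reference-slides-into-the-peak situation (cf. a
#' ceramide-like 2880 band against CH3-dominant pixels). With per-pixel
#' spectral jitter present: an under-weighted penalty lets `phase_b` pixels
#' reach the satellite alignment and inflate their score against `phase_a`;
#' an over-weighted penalty taxes the genuine jitter of `phase_a` pixels.
#' Matched-vs-unmatched contrast therefore peaks at an intermediate
#' coefficient. Synthetic stand-ins, not measured spectra.
#'
#' @return Named list of two peak lists (`phase_a`, `phase_b`) for
#'   [make_reference()].
#' @export
penalty_demo_peak_sets <- function() {
  list(
    phase_a = list(c(1.00, 2850, 6), c(0.70, 2935, 6)),
    phase_b = list(c(1.00, 2760, 8), c(0.03, 2870, 3))
  )
}

#' Build the demo reference library
#'
#' Convenience wrapper: generates the [demo_peak_sets()] spectra on the fine
#' grid and preprocesses them into a [reference_library()].
#'
#' @param cfg A `preprocess_config`.
#' @return A `reference_library` with entries `tag_like`, `pe_like`,
#'   `chol_like`.
#' @export
demo_library <- function(cfg = preprocess_config()) {
  ps <- demo_peak_sets()
  grid <- grid_axis(cfg)
  raw <- lapply(names(ps), function(nm) make_reference(ps[[nm]], grid, label = nm))
  names(raw) <- names(ps)
  build_library(raw, cfg)
}

# ground-truth weight array (nrow x ncol x n_refs) for a layout
layout_weights <- function(spec, n_refs) {
  w <- array(0, dim = c(spec$nrow, spec$ncol, n_refs))
  half <- ceiling(spec$ncol / 2)
  if (spec$layout == "two_phase") {
    if (n_refs < 2) stop("two_phase layout needs at least 2 references", call. = FALSE)
    w[, seq_len(half), 1] <- 1
    w[, (half + 1):spec$ncol, 2] <- 1
  } else if (spec$layout == "fraction_ramp") {
    if (n_refs < 2) stop("fraction_ramp layout needs at least 2 references", call. = FALSE)
    f <- if (spec$ncol == 1) 1 else (seq_len(spec$ncol) - 1) / (spec$ncol - 1)
    for (j in seq_len(spec$ncol)) {
      w[, j, 1] <- f[j]
      w[, j, 2] <- 1 - f[j]
    }
  } else {  # droplets
    if (n_refs < 2) stop("droplets layout needs at least 2 references", call. = FALSE)
    w[, , 1] <- 1
    # deterministic droplet placement (drawn inside with_local_seed upstream)
    n_drop <- max(1L, round(spec$nrow * spec$ncol / 85))
    r_drop <- max(2, round(min(spec$nrow, spec$ncol) / 6))
    for (k in seq_len(n_drop)) {
      cy <- stats::runif(1, 1 + r_drop, spec$nrow - r_drop)
      cx <- stats::runif(1, 1 + r_drop, spec$ncol - r_drop)
      for (i in seq_len(spec$nrow)) for (j in seq_len(spec$ncol)) {
        if ((i - cy)^2 + (j - cx)^2 <= r_drop^2) {
          w[i, j, 1] <- 0
          w[i, j, 2] <- 1
        }
      }
    }
  }
  w
}

#' Generate a synthetic hyperspectral stack with ground truth
#'
#' Per pixel: the weighted mixture of the library spectra is scaled by a
#' random brightness factor, shifted along the wavenumber axis by a normal
#' spectral jitter (linear re-interpolation on the fine grid, edge values
#' extended), perturbed by additive Gaussian noise (clamped at zero, as a
#' detector would), and finally resampled to the coarser acquired band axis.
#' Ground-truth weight, shift and brightness maps are returned alongside the
#' stack; everything is reproducible from `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @param lib A `reference_library` on the fine simulation grid.
#' @return A list: `stack` (`hsi_stack` on the acquired band axis),
#'   `weights` (nrow x ncol x n_refs array, dimnames carry reference
#'   names), `shift_map`, `brightness_map`, `band_axis`.
#' @export
make_stack <- function(spec, lib) {
  stopifnot(inherits(spec, "sim_spec"), inherits(lib, "reference_library"))
  fine <- seq(spec$grid_range[1], spec$grid_range[2], by = spec$grid_step)
  if (length(lib$grid) != length(fine) || any(lib$grid != fine)) {
    stop("library must live on the simulation grid", call. = FALSE)
  }
  n_refs <- length(lib$entries)
  R <- vapply(lib$entries, function(e) e$intensity, numeric(length(fine)))
  band_axis <- seq(spec$grid_range[1], by = spec$band_step,
                   length.out = spec$n_bands)

  with_local_seed(spec$seed, {
    w <- layout_weights(spec, n_refs)
    bad <- abs(apply(w, c(1, 2), sum) - 1) > 1e-9
    if (any(bad)) stop("per-pixel weights must sum to 1", call. = FALSE)
    n_pix <- spec$nrow * spec$ncol
    bright <- matrix(stats::runif(n_pix, spec$brightness_range[1],
                                  spec$brightness_range[2]),
                     spec$nrow, spec$ncol)
    jit <- matrix(stats::rnorm(n_pix, 0, spec$jitter_sd), spec$nrow, spec$ncol)
    data <- array(0, dim = c(spec$nrow, spec$ncol, spec$n_bands))
    for (i in seq_len(spec$nrow)) {
      for (j in seq_len(spec$ncol)) {
        mix <- as.numeric(R %*% w[i, j, ]) * bright[i, j]
        if (spec$jitter_sd > 0 && jit[i, j] != 0) {
          # shift by +d: value at x comes from the unshifted spectrum at x - d
          mix <- stats::approx(fine, mix, xout = fine - jit[i, j], rule = 2)$y
        }
        if (spec$noise_sd > 0) {
          mix <- mix + stats::rnorm(length(mix), 0, spec$noise_sd)
        }
        mix <- pmax(mix, 0)
        data[i, j, ] <- stats::approx(fine, mix, xout = band_axis)$y
      }
    }
    dimnames(w) <- list(NULL, NULL, names(lib$entries))
    list(stack = hsi_stack(data, band_axis,
                           meta = list(synthetic = TRUE, seed = spec$seed,
                                       layout = spec$layout)),
         weights = w, shift_map = jit, brightness_map = bright,
         band_axis = band_axis)
  })
}

#' Two-component fraction series with ground truth
#'
#' Spectra `f * a + (1 - f) * b` for each fraction `f`, with optional
#' additive Gaussian noise — the input for score-versus-concentration
#' monotonicity checks.
#'
#' @param ref_a,ref_b `raman_spectrum` objects on a common axis (any stage;
#'   mixed as-is).
#' @param fractions Numeric vector of weights on `ref_a`, each in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise s.d. (default 0).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return A list: `spectra` (list of raw-stage `raman_spectrum`),
#'   `fractions`.
#' @export
make_fraction_series <- function(ref_a, ref_b, fractions = seq(0, 1, by = 0.1),
                                 noise_sd = 0, seed = 0L) {
  stopifnot(inherits(ref_a, "raman_spectrum"), inherits(ref_b, "raman_spectrum"),
            all(fractions >= 0 & fractions <= 1),
            length(ref_a$wavenumber) == length(ref_b$wavenumber),
            all(ref_a$wavenumber == ref_b$wavenumber))
  with_local_seed(seed, {
    spectra <- lapply(fractions, function(f) {
      y <- f * ref_a$intensity + (1 - f) * ref_b$intensity
      if (noise_sd > 0) y <- pmax(y + stats::rnorm(length(y), 0, noise_sd), 0)
      raman_spectrum(ref_a$wavenumber, y, stage = "raw",
                     label = sprintf("f=%.2f", f))
    })
    list(spectra = spectra, fractions = fractions)
  })
}
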