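gauss_sum <- function(x, a, cen, w) {
  y <- numeric(length(x))
  for (k in seq_along(a)) y <- y + a[k] * exp(-(x - cen[k])^2 / (2 * w[k]^2))
  y
}

#' Decompose a CH-region spectrum into four Gaussian components
#'
#' Bounded nonlinear least squares of a sum of four Gaussians
#' `a * exp(-(x - c)^2 / (2 w^2))` over the fit window. Default initial
#' centers sit on the canonical CH-stretching bands: 2850 (CH2 symmetric),
#' 2880 (CH2 asymmetric / Fermi resonance), 2935 (CH3), 3065 (olefinic
#' =C-H) cm^-1. Amplitudes are bounded below by 0, centers confined to the
#' window, widths to \[2, 100\] cm^-1.
#'
#' @param s A `raman_spectrum` covering the window (typically min-max
#'   normalized; the fit is scale-equivariant).
#' @param window Fit window `c(lo, hi)` in cm^-1, default `c(2700, 3150)`.
#' @param init Optional numeric vector of 4 initial centers.
#' @return An object of class `gaussian_fit`: `components` (4-row data frame
#'   with `amplitude`, `center`, `width`, sorted by center), `rss`,
#'   `converged`.
#' @export
fit_four_gaussians <- function(s, window = c(2700, 3150), init = NULL) {
  stopifnot(inherits(s, "raman_spectrum"), length(window) == 2,
            window[1] < window[2])
  keep <- s$wavenumber >= window[1] & s$wavenumber <= window[2]
  if (sum(keep) < 13L) stop("spectrum does not cover the fit window", call. = FALSE)
  x <- s$wavenumber[keep]
  y <- s$intensity[keep]

  centers0 <- if (is.null(init)) c(2850, 2880, 2935, 3065) else as.numeric(init)
  stopifnot(length(centers0) == 4)
  centers0 <- pmin(pmax(centers0, window[1]), window[2])
  amp0 <- vapply(centers0, function(cc) max(y[which.min(abs(x - cc))], 1e-6),
                 numeric(1))
  p0 <- c(amp0, centers0, rep(15, 4))
  lower <- c(rep(0, 4), rep(window[1], 4), rep(2, 4))
  upper <- c(rep(Inf, 4), rep(window[2], 4), rep(100, 4))

  resid_fn <- function(p) y - gauss_sum(x, p[1:4], p[5:8], p[9:12])
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  ord <- order(p[5:8])
  comps <- data.frame(amplitude = p[1:4][ord],
                      center = p[5:8][ord],
                      width = p[9:12][ord])
  structure(list(components = comps,
                 rss = sum(resid_fn(p)^2),
                 converged = fit$info %in% 1:3),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> rss %.4g%s\n", x$rss,
              if (x$converged) "" else " (not converged)"))
  print(round(x$components, 3))
  invisible(x)
}

#' Evaluate a Gaussian fit on an axis
#'
#' @param fit A `gaussian_fit`.
#' @param x Wavenumber axis.
#' @return Fitted intensities.
#' @export
predict_gaussians <- function(fit, x) {
  with(fit$components, gauss_sum(x, amplitude, center, width))
}

#' Fit every library entry with four Gaussians
#'
#' @param lib A `reference_library`.
#' @param window Fit window, as in [fit_four_gaussians()].
#' @return A data frame with one row per entry: `name`, `a1..a4`, `c1..c4`,
#'   `w1..w4` (components sorted by center), `rss`, `converged`. A per-entry
#'   failure is recorded as a flagged row of `NA` parameters rather than
#'   aborting the table.
#' @export
fit_library <- function(lib, window = c(2700, 3150)) {
  stopifnot(inherits(lib, "reference_library"))
  if (length(lib$entries) == 0) {
    cols <- c("name", paste0("a", 1:4), paste0("c", 1:4), paste0("w", 1:4),
              "rss", "converged")
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    out$name <- character(0)
    out$converged <- logical(0)
    return(out)
  }
  rows <- lapply(names(lib$entries), function(nm) {
    res <- tryCatch(fit_four_gaussians(lib$entries[[nm]], window),
                    error = function(e) NULL)
    if (is.null(res)) {
      as.data.frame(c(list(name = nm),
                      stats::setNames(as.list(rep(NA_real_, 12)),
                                      c(paste0("a", 1:4), paste0("c", 1:4),
                                        paste0("w", 1:4))),
                      list(rss = NA_real_, converged = FALSE)))
    } else {
      cm <- res$components
      as.data.frame(c(list(name = nm),
                      stats::setNames(as.list(cm$amplitude), paste0("a", 1:4)),
                      stats::setNames(as.list(cm$center), paste0("c", 1:4)),
                      stats::setNames(as.list(cm$width), paste0("w", 1:4)),
                      list(rss = res$rss, converged = res$converged)))
    }
  })
  do.call(rbind, rows)
}
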