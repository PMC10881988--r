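#' Pseudo-inverse (PINV) unmixing of one pixel spectrum
#'
#' Linear least-squares baseline against which the bounded PRM score is
#' compared: solves `min ||R c - s||_2` where the columns of `R` are the
#' library's unit-norm reference spectra. Coefficients are unbounded and may
#' be negative; a rank-deficient reference matrix falls back to the
#' Moore-Penrose minimum-norm solution with a warning.
#'
#' @param pixel A `raman_spectrum` on the library grid (stage `"unit_norm"`
#'   for comparability with PRM preprocessing, though any stage is accepted).
#' @param lib A `reference_library`.
#' @return An object of class `pinv_result`: `coefficients` (named, one per
#'   library entry), `residual_norm`, and `rank_deficient` flag.
#' @export
pinv_unmix <- function(pixel, lib) {
  stopifnot(inherits(pixel, "raman_spectrum"), inherits(lib, "reference_library"))
  if (length(lib$entries) == 0) stop("empty reference library", call. = FALSE)
  if (length(pixel$wavenumber) != length(lib$grid) ||
      any(pixel$wavenumber != lib$grid)) {
    stop("pixel must be on the library grid", call. = FALSE)
  }
  R <- vapply(lib$entries, function(e) e$intensity, numeric(length(lib$grid)))
  s <- pixel$intensity
  dec <- qr(R)
  rank_deficient <- dec$rank < ncol(R)
  if (rank_deficient) {
    warning("rank-deficient reference matrix; returning minimum-norm solution",
            call. = FALSE)
    cf <- as.numeric(MASS::ginv(R) %*% s)
  } else {
    cf <- as.numeric(qr.coef(dec, s))
  }
  names(cf) <- names(lib$entries)
  resid <- sqrt(sum((as.numeric(R %*% cf) - s)^2))
  structure(list(coefficients = cf, residual_norm = resid,
                 rank_deficient = rank_deficient),
            class = "pinv_result")
}

#' @export
print.pinv_result <- function(x, ...) {
  cat("<pinv_result>\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  residual norm %.3g%s\n", x$residual_norm,
              if (x$rank_deficient) " (rank deficient)" else ""))
  invisible(x)
}

#' PINV unmixing of every pixel in a stack
#'
#' Per-pixel least squares against the library (each pixel solved
#' independently, so a pixel's coefficients do not depend on the image it is
#' embedded in). Pixels are preprocessed with the same chain as PRM scoring
#' so the two baselines see identical inputs. Elapsed wall time is attached
#' so PRM-vs-PINV runtime can be compared locally.
#'
#' @param stack An `hsi_stack`.
#' @param lib A `reference_library` on the preprocessing grid.
#' @param pcfg A `preprocess_config`.
#' @param background Optional background for `baseline = "subtract_measured"`.
#' @return A list: `coefficients` (named list of rows x cols matrices, one
#'   per reference; masked pixels hold `NA`), `mask`, `residual_norm`
#'   matrix, and `elapsed_sec`.
#' @export
pinv_unmix_stack <- function(stack, lib, pcfg = preprocess_config(),
                             background = NULL) {
  stopifnot(inherits(lib, "reference_library"))
  if (length(lib$entries) == 0) stop("empty reference library", call. = FALSE)
  grid <- grid_axis(pcfg)
  if (length(lib$grid) != length(grid) || any(lib$grid != grid)) {
    stop("library grid does not match the preprocessing grid", call. = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]
  pp <- preprocess_stack_matrix(stack, pcfg, background)
  R <- vapply(lib$entries, function(e) e$intensity, numeric(length(grid)))
  dec <- qr(R)
  if (dec$rank < ncol(R)) {
    warning("rank-deficient reference matrix; returning minimum-norm solution",
            call. = FALSE)
    C <- MASS::ginv(R) %*% t(pp$P)
  } else {
    C <- qr.coef(dec, t(pp$P))
  }
  resid <- sqrt(colSums((R %*% C - t(pp$P))^2))
  elapsed <- proc.time()[["elapsed"]] - t0
  shape <- pp$shape
  coef_maps <- lapply(seq_along(lib$entries), function(k) {
    m <- matrix(C[k, ], shape[1], shape[2])
    m[matrix(pp$mask, shape[1], shape[2])] <- NA_real_
    m
  })
  names(coef_maps) <- names(lib$entries)
  rn <- matrix(resid, shape[1], shape[2])
  rn[matrix(pp$mask, shape[1], shape[2])] <- NA_real_
  list(coefficients = coef_maps,
       mask = matrix(pp$mask, shape[1], shape[2]),
       residual_norm = rn,
       elapsed_sec = elapsed)
}
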