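#' PRM configuration
#'
#' Settings for the penalized reference-matching score: the quadratic shift
#' penalty coefficient and the discrete shift-search grid.
#'
#' @param alpha Penalty coefficient in cm^2; the penalty subtracted at a
#'   spectral offset of `dx` cm^-1 is `alpha * dx^2`. Default `1e-4`:
#'   at this weight a 30 cm^-1 offset costs 0.09 score units. Larger values
#'   over-penalize (approaching plain unshifted cosine matching), smaller
#'   values let spectra slide freely and saturate the score.
#' @param max_shift Maximum absolute spectral offset searched, cm^-1
#'   (default 30).
#' @param shift_step Offset grid spacing, cm^-1 (default 1, matching the
#'   interpolation grid). Must divide `max_shift`.
#' @param tie_break Tie-breaking rule at equal maxima; `"smallest_abs_shift"`
#'   prefers the smallest `|dx|`, then the negative offset.
#' @return An object of class `prm_config`.
#' @export
prm_config <- function(alpha = 1e-4, max_shift = 30, shift_step = 1,
                       tie_break = "smallest_abs_shift") {
  tie_break <- match.arg(tie_break)
  stopifnot(alpha >= 0, max_shift >= 0, shift_step > 0)
  if (max_shift %% shift_step > 1e-9 &&
      shift_step - (max_shift %% shift_step) > 1e-9) {
    stop("shift_step must divide max_shift", call. = FALSE)
  }
  structure(list(alpha = alpha, max_shift = max_shift,
                 shift_step = shift_step, tie_break = tie_break),
            class = "prm_config")
}

# offset grid in cm^-1, ordered ascending
shift_grid <- function(cfg) {
  if (cfg$max_shift == 0) return(0)
  seq(-cfg$max_shift, cfg$max_shift, by = cfg$shift_step)
}

# tie-break evaluation order: smallest |dx| first, negative before positive
shift_order <- function(dx) order(abs(dx), dx)

# slide v by k grid positions (positive = toward higher wavenumber),
# zero-padding the vacated leading side and trimming the overhang
shift_vector <- function(v, k) {
  n <- length(v)
  if (k == 0) return(v)
  if (abs(k) >= n) return(numeric(n))
  if (k > 0) c(numeric(k), v[seq_len(n - k)]) else c(v[(1 - k):n], numeric(-k))
}

# matrix whose columns are the reference slid by each offset in dx_cm
shifted_reference_matrix <- function(ref_vec, dx_cm, grid_step) {
  ks <- dx_cm / grid_step
  if (any(abs(ks - round(ks)) > 1e-9)) {
    stop("shift_step must be an integer multiple of the interpolation grid step",
         call. = FALSE)
  }
  vapply(as.integer(round(ks)), function(k) shift_vector(ref_vec, k),
         numeric(length(ref_vec)))
}

#' Penalized reference-matching score of one spectrum
#'
#' Evaluates, for every offset `dx` on the shift grid, the inner product of
#' the pixel spectrum with the reference slid by `dx` (zero-padded on the
#' leading side, trimmed on the lagging side) minus the quadratic penalty
#' `alpha * dx^2`, and returns the maximum. With both spectra at unit norm
#' the unshifted term is a cosine similarity, so for nonnegative spectra the
#' score always lies in `[0, 1]`.
#'
#' @param pixel A `raman_spectrum` at stage `"unit_norm"`.
#' @param ref A `raman_spectrum` at stage `"unit_norm"` on the same axis.
#' @param cfg A `prm_config`.
#' @param return_trace If `TRUE`, include the full per-offset score curve.
#' @return An object of class `prm_result`: `score`, `best_shift` (signed
#'   cm^-1; positive = reference moved toward higher wavenumber), `masked`
#'   flag, and optionally `per_shift_scores` (named by offset).
#' @examples
#' cfg <- preprocess_config()
#' r <- preprocess_reference(make_reference(list(c(1, 2935, 20))), cfg)
#' prm_score(r, r)$score  # exact match: 1
#' @export
prm_score <- function(pixel, ref, cfg = prm_config(), return_trace = FALSE) {
  stopifnot(inherits(pixel, "raman_spectrum"), inherits(ref, "raman_spectrum"),
            inherits(cfg, "prm_config"))
  if (length(pixel$wavenumber) != length(ref$wavenumber) ||
      any(pixel$wavenumber != ref$wavenumber)) {
    stop("pixel and reference must share the same axis (same grid)", call. = FALSE)
  }
  if (pixel$stage != "unit_norm" || ref$stage != "unit_norm") {
    stop("prm_score expects unit_norm spectra; run preprocess_pixel first",
         call. = FALSE)
  }
  grid_step <- pixel$wavenumber[2] - pixel$wavenumber[1]
  dx <- shift_grid(cfg)
  R <- shifted_reference_matrix(ref$intensity, dx, grid_step)
  trace <- as.numeric(crossprod(R, pixel$intensity)) - cfg$alpha * dx^2
  ord <- shift_order(dx)
  best <- ord[which.max(trace[ord])]  # which.max takes the first maximum
  res <- list(score = min(max(trace[best], 0), 1),
              best_shift = dx[best], masked = FALSE)
  if (return_trace) res$per_shift_scores <- stats::setNames(trace, dx)
  structure(res, class = "prm_result")
}

#' @export
print.prm_result <- function(x, ...) {
  cat(sprintf("<prm_result> score %.4f at shift %+g cm-1%s\n",
              x$score, x$best_shift, if (x$masked) " (masked)" else ""))
  invisible(x)
}

# --- shared stack preprocessing -------------------------------------------

.prm_counters <- new.env(parent = emptyenv())
.prm_counters$preprocessed_pixels <- 0

#' Instrumentation counters
#'
#' `prm_counters()` returns the cumulative number of pixel spectra run
#' through the preprocessing chain; `reset_prm_counters()` zeroes it. Used to
#' verify that multi-reference scoring preprocesses each pixel once, not once
#' per reference.
#' @return `prm_counters()`: a list of counters.
#' @export
prm_counters <- function() {
  list(preprocessed_pixels = .prm_counters$preprocessed_pixels)
}

#' @rdname prm_counters
#' @export
reset_prm_counters <- function() {
  .prm_counters$preprocessed_pixels <- 0
  invisible(NULL)
}

# Preprocess every pixel of a stack onto the grid; returns the n_pixels x
# n_grid unit-norm matrix, the degenerate-pixel mask and the grid axis.
# Vectorized: interpolation is one sparse-matrix product; min-max and
# Euclidean normalization are row operations.
preprocess_stack_matrix <- function(stack, pcfg, background = NULL) {
  stopifnot(inherits(stack, "hsi_stack"), inherits(pcfg, "preprocess_config"))
  d <- dim(stack$data)
  n_pix <- d[1] * d[2]
  P <- matrix(stack$data, nrow = n_pix, ncol = d[3])
  axis <- stack$wavenumber

  if (pcfg$baseline == "subtract_measured") {
    if (is.null(background)) {
      stop("baseline 'subtract_measured' requires a background spectrum", call. = FALSE)
    }
    stopifnot(length(background$wavenumber) == d[3],
              all(background$wavenumber == axis))
    P <- sweep(P, 2, background$intensity)
  } else if (pcfg$baseline == "arpls") {
    for (i in seq_len(n_pix)) {
      P[i, ] <- P[i, ] - arpls_fit(P[i, ], pcfg$arpls_lambda,
                                   pcfg$arpls_ratio, pcfg$arpls_max_iter)
    }
  }

  grid <- grid_axis(pcfg)
  inside <- grid >= min(axis) & grid <= max(axis)
  if (!any(inside)) stop("stack axis does not overlap the grid range", call. = FALSE)
  # linear interpolation as a sparse bands x grid weight matrix
  gi <- which(inside)
  j <- findInterval(grid[gi], axis, rightmost.closed = TRUE)
  j <- pmin(j, length(axis) - 1L)
  t_ <- (grid[gi] - axis[j]) / (axis[j + 1L] - axis[j])
  W <- Matrix::sparseMatrix(
    i = c(j, j + 1L), j = c(gi, gi), x = c(1 - t_, t_),
    dims = c(length(axis), length(grid))
  )
  G <- as.matrix(P %*% W)

  rmin <- apply(G, 1, min)
  rmax <- apply(G, 1, max)
  mask <- (rmax - rmin) <= 0
  span <- ifelse(mask, 1, rmax - rmin)
  G <- (G - rmin) / span
  nrm <- sqrt(rowSums(G^2))
  mask <- mask | nrm <= 0
  G <- G / ifelse(mask, 1, nrm)
  G[mask, ] <- 0

  .prm_counters$preprocessed_pixels <- .prm_counters$preprocessed_pixels + n_pix
  list(P = G, mask = mask, grid = grid, shape = d[1:2], grid_coverage = inside)
}

# ensure a reference is unit_norm on the pcfg grid
prepare_reference <- function(ref, pcfg) {
  grid <- grid_axis(pcfg)
  if (ref$stage == "unit_norm" && length(ref$wavenumber) == length(grid) &&
      all(ref$wavenumber == grid)) {
    return(ref)
  }
  preprocess_reference(ref, pcfg)
}

# score a preprocessed pixel matrix against one reference vector
score_pixel_matrix <- function(P, mask, ref_vec, cfg, grid_step, chunk_size = NULL) {
  dx <- shift_grid(cfg)
  R <- shifted_reference_matrix(ref_vec, dx, grid_step)
  pen <- cfg$alpha * dx^2
  ord <- shift_order(dx)
  n_pix <- nrow(P)
  if (is.null(chunk_size)) chunk_size <- 8192L
  scores <- numeric(n_pix)
  shifts <- numeric(n_pix)
  start <- 1L
  while (start <= n_pix) {
    idx <- start:min(start + chunk_size - 1L, n_pix)
    Pc <- P[idx, , drop = FALSE]
    best <- rep(-Inf, length(idx))
    bshift <- numeric(length(idx))
    for (ci in ord) {  # preferred shifts first: strict > keeps the tie-break
      # rowSums accumulates each pixel's dot product in fixed column order,
      # so the result is bit-identical under any chunk decomposition (a BLAS
      # product would change its accumulation with the chunk height)
      s_ci <- rowSums(Pc * rep(R[, ci], each = length(idx))) - pen[ci]
      upd <- s_ci > best
      best[upd] <- s_ci[upd]
      bshift[upd] <- dx[ci]
    }
    scores[idx] <- best
    shifts[idx] <- bshift
    start <- start + chunk_size
  }
  scores <- pmin(pmax(scores, 0), 1)
  scores[mask] <- 0
  shifts[mask] <- 0
  list(scores = scores, shifts = shifts)
}

#' Score every pixel of a stack against one reference
#'
#' Preprocesses each pixel spectrum (baseline, common-grid interpolation,
#' min-max and Euclidean normalization) and computes the penalized
#' reference-matching score against the reference. The result is independent
#' of the chunking used for the matrix products; degenerate pixels (constant
#' or zero spectra) are masked with score 0.
#'
#' @param stack An `hsi_stack`.
#' @param ref A `raman_spectrum` (raw spectra are preprocessed with `pcfg`
#'   automatically; unit-norm spectra already on the grid are used as-is).
#' @param pcfg A `preprocess_config`.
#' @param cfg A `prm_config`.
#' @param background Optional measured background for
#'   `baseline = "subtract_measured"`.
#' @param chunk_size Optional number of pixels per processing block (memory
#'   knob only; output is bit-identical for any value).
#' @return A [score_image()].
#' @export
score_stack <- function(stack, ref, pcfg = preprocess_config(),
                        cfg = prm_config(), background = NULL,
                        chunk_size = NULL) {
  pp <- preprocess_stack_matrix(stack, pcfg, background)
  ref <- prepare_reference(ref, pcfg)
  sc <- score_pixel_matrix(pp$P, pp$mask, ref$intensity, cfg,
                           pcfg$grid_step, chunk_size)
  img <- score_image(matrix(sc$scores, pp$shape[1], pp$shape[2]),
                     matrix(sc$shifts, pp$shape[1], pp$shape[2]),
                     matrix(pp$mask, pp$shape[1], pp$shape[2]),
                     reference_name = ref$label, config = cfg)
  # grid points outside the stack's band range were zero-filled; keep the flag
  attr(img, "grid_coverage") <- pp$grid_coverage
  img
}

#' Score a stack against every library entry
#'
#' Pixel preprocessing is performed once and reused across all references
#' (one preprocessing pass per pixel, not one per pixel-reference pair).
#'
#' @param stack An `hsi_stack`.
#' @param lib A `reference_library`.
#' @inheritParams score_stack
#' @return Named list of [score_image()], one per library entry.
#' @export
score_stack_multi <- function(stack, lib, pcfg = preprocess_config(),
                              cfg = prm_config(), background = NULL,
                              chunk_size = NULL) {
  stopifnot(inherits(lib, "reference_library"))
  if (length(lib$entries) == 0) stop("empty reference library", call. = FALSE)
  grid <- grid_axis(pcfg)
  if (length(lib$grid) != length(grid) || any(lib$grid != grid)) {
    stop("library grid does not match the preprocessing grid", call. = FALSE)
  }
  pp <- preprocess_stack_matrix(stack, pcfg, background)
  out <- lapply(names(lib$entries), function(nm) {
    sc <- score_pixel_matrix(pp$P, pp$mask, lib$entries[[nm]]$intensity, cfg,
                             pcfg$grid_step, chunk_size)
    score_image(matrix(sc$scores, pp$shape[1], pp$shape[2]),
                matrix(sc$shifts, pp$shape[1], pp$shape[2]),
                matrix(pp$mask, pp$shape[1], pp$shape[2]),
                reference_name = nm, config = cfg)
  })
  stats::setNames(out, names(lib$entries))
}
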