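as_score_matrix <- function(x) {
  if (inherits(x, "score_image")) x$scores else as.matrix(x)
}

as_score_mask <- function(x) {
  if (inherits(x, "score_image")) x$mask
  else matrix(FALSE, nrow(as.matrix(x)), ncol(as.matrix(x)))
}

#' Ratiometric image of two score maps
#'
#' Pixelwise `num / den`, revealing relative subtype abundance independent
#' of overall intensity. Pixels where the denominator falls below `epsilon`,
#' plus the union of the input masks, are masked (`NA`) rather than allowed
#' to blow up.
#'
#' @param num,den `score_image` objects (or plain matrices) of equal shape.
#' @param epsilon Denominator floor (default 1e-6).
#' @return An object of class `ratio_image`: `values` (matrix, `NA` where
#'   masked), `mask`, `numerator_name`, `denominator_name`, `epsilon`.
#' @export
ratio_image <- function(num, den, epsilon = 1e-6) {
  a <- as_score_matrix(num)
  b <- as_score_matrix(den)
  if (!all(dim(a) == dim(b))) stop("score maps differ in shape", call. = FALSE)
  mask <- as_score_mask(num) | as_score_mask(den) | b < epsilon
  vals <- a / b
  vals[mask] <- NA_real_
  structure(list(values = vals, mask = mask,
                 numerator_name = if (inherits(num, "score_image")) num$reference_name else "",
                 denominator_name = if (inherits(den, "score_image")) den$reference_name else "",
                 epsilon = epsilon),
            class = "ratio_image")
}

#' @export
print.ratio_image <- function(x, ...) {
  ok <- !x$mask
  cat(sprintf("<ratio_image> %s / %s: %d x %d, %d masked (epsilon %g)\n",
              x$numerator_name, x$denominator_name,
              nrow(x$values), ncol(x$values), sum(x$mask), x$epsilon))
  if (any(ok)) cat(sprintf("  range %.4f-%.4f\n", min(x$values[ok]), max(x$values[ok])))
  invisible(x)
}

#' Threshold a score map into a binary mask
#'
#' @param score A `score_image` (or matrix).
#' @param t Threshold in `[0, 1]`; pixels with score >= `t` are `TRUE`.
#'   Masked pixels are always `FALSE`.
#' @return Logical matrix. Monotone in `t`: raising the threshold can only
#'   shrink the mask.
#' @export
threshold_mask <- function(score, t) {
  stopifnot(t >= 0)
  m <- as_score_matrix(score) >= t & !as_score_mask(score)
  m
}

#' Mean spectrum of the top-scoring pixels
#'
#' Selects the pixels whose similarity score reaches the `pct`-th percentile
#' (linear-interpolation percentile over unmasked scores) and returns the
#' mean of their preprocessed (unit-norm) spectra with the per-band standard
#' deviation — the way a "top 10%" pixel population is summarized against
#' its reference.
#'
#' @param stack The `hsi_stack` the scores were computed from.
#' @param score The corresponding `score_image`.
#' @param pct Percentile in (0, 100); e.g. 90 selects the top decile.
#' @param pcfg The `preprocess_config` used for scoring.
#' @param background Optional background for `baseline = "subtract_measured"`.
#' @return A list: `mean_spectrum` (a `raman_spectrum`; the mean of
#'   unit-norm pixel spectra, so its own norm is <= 1), `sd` (per-band
#'   standard deviation), `n_selected`, `threshold`.
#' @export
top_percentile_spectra <- function(stack, score, pct = 90,
                                   pcfg = preprocess_config(),
                                   background = NULL) {
  stopifnot(inherits(score, "score_image"), pct > 0, pct < 100)
  if (!all(dim(stack$data)[1:2] == dim(score$scores))) {
    stop("stack and score image are not co-registered", call. = FALSE)
  }
  ok <- !score$mask
  if (!any(ok)) stop("all pixels are masked; empty selection", call. = FALSE)
  thr <- stats::quantile(score$scores[ok], pct / 100, names = FALSE, type = 7)
  sel_img <- score$scores >= thr & ok
  pp <- preprocess_stack_matrix(stack, pcfg, background)
  sel <- as.vector(sel_img)
  M <- pp$P[sel, , drop = FALSE]
  mu <- colMeans(M)
  sdev <- if (nrow(M) > 1) apply(M, 2, stats::sd) else numeric(ncol(M)) * 0
  list(mean_spectrum = raman_spectrum(pp$grid, mu, stage = "raw",
                                      label = sprintf("mean of top %g%% pixels", 100 - pct)),
       sd = sdev, n_selected = nrow(M), threshold = thr)
}

#' Merge score maps into an additive color composite
#'
#' Each score map is assigned a color; the composite is the per-channel sum
#' of `score * rgb`, with fixed \[0, 1\] scaling per channel (no per-image
#' stretch, so composites stay comparable across stacks). Channel values
#' exceeding 1 are clipped and the clip count recorded.
#'
#' @param images List of `score_image` objects (or matrices) of equal shape.
#' @param colors Vector of R color names/hex, or a list of RGB triplets in
#'   `[0, 1]`, one per image.
#' @return A rows x cols x 3 array in `[0, 1]` with attribute
#'   `"n_clipped"` (number of clipped channel values).
#' @export
merge_channels <- function(images, colors) {
  stopifnot(length(images) >= 1, length(colors) == length(images))
  mats <- lapply(images, as_score_matrix)
  d <- dim(mats[[1]])
  for (m in mats) if (!all(dim(m) == d)) stop("shape mismatch", call. = FALSE)
  rgb_list <- lapply(colors, function(cl) {
    if (is.numeric(cl)) {
      stopifnot(length(cl) == 3)
      as.numeric(cl)
    } else {
      as.numeric(grDevices::col2rgb(cl)) / 255
    }
  })
  comp <- array(0, dim = c(d, 3L))
  for (k in seq_along(mats)) {
    m <- mats[[k]]
    m[as_score_mask(images[[k]])] <- 0
    for (ch in 1:3) comp[, , ch] <- comp[, , ch] + m * rgb_list[[k]][ch]
  }
  n_clipped <- sum(comp > 1)
  comp[comp > 1] <- 1
  attr(comp, "n_clipped") <- n_clipped
  comp
}

# centered 7x7 uniform mean filter; boundary rows/cols become NA and are
# cropped by the caller, so every retained value has full in-image support
uniform7 <- function(m) {
  f <- rep(1 / 7, 7)
  a <- apply(m, 2, function(col) stats::filter(col, f, sides = 2))
  t(apply(a, 1, function(row) stats::filter(row, f, sides = 2)))
}

#' Agreement between two images
#'
#' Computes a structural similarity index and the normalized mean squared
#' error, the pair of metrics used to compare a score map against a second
#' imaging modality (e.g. a fluorescence channel). Inputs are jointly
#' min-max scaled to \[0, 1\] first, so the metrics respond to pattern, not
#' units. The similarity index uses the standard formulation: 7x7 uniform
#' local windows, sample covariances, constants `C1 = 0.01^2`,
#' `C2 = 0.03^2` on the unit dynamic range, averaged over the region where
#' the window fits entirely inside the image.
#'
#' @param a,b Numeric matrices of equal shape (at least 7x7), finite.
#' @return A list: `similarity_index` in `(-1, 1]` and `nmse`
#'   (`||a - b||^2 / ||b||^2`, computed on the scaled images). `b`
#'   identically zero after scaling makes `nmse` undefined (error).
#' @export
image_agreement <- function(a, b) {
  a <- as_score_matrix(a)
  b <- as_score_matrix(b)
  if (!all(dim(a) == dim(b))) stop("images differ in shape", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("images must be finite", call. = FALSE)
  if (any(dim(a) < 7L)) stop("images must be at least 7 x 7", call. = FALSE)
  lo <- min(a, b)
  hi <- max(a, b)
  if (hi > lo) {
    a <- (a - lo) / (hi - lo)
    b <- (b - lo) / (hi - lo)
  }
  bn <- sum(b^2)
  if (bn == 0) stop("nmse undefined: reference image is constant zero", call. = FALSE)
  nmse <- sum((a - b)^2) / bn

  C1 <- 0.01^2
  C2 <- 0.03^2
  N <- 49
  cov_norm <- N / (N - 1)
  ux <- uniform7(a); uy <- uniform7(b)
  uxx <- uniform7(a * a); uyy <- uniform7(b * b); uxy <- uniform7(a * b)
  vx <- cov_norm * (uxx - ux * ux)
  vy <- cov_norm * (uyy - uy * uy)
  vxy <- cov_norm * (uxy - ux * uy)
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
       ((ux * ux + uy * uy + C1) * (vx + vy + C2))
  pad <- 3L
  core <- S[(pad + 1):(nrow(S) - pad), (pad + 1):(ncol(S) - pad)]
  list(similarity_index = mean(core), nmse = nmse)
}

#' Intensity profile along a line segment
#'
#' Bilinearly samples an image along the segment from `p0` to `p1` at
#' approximately unit spacing: `ceil(d) + 1` evenly spaced points for a
#' segment of Euclidean length `d`.
#'
#' @param img Numeric matrix (or `score_image`).
#' @param p0,p1 Endpoints as `c(row, col)`, 1-based, inside the image.
#' @return Numeric vector of sampled values.
#' @export
line_profile <- function(img, p0, p1) {
  m <- as_score_matrix(img)
  stopifnot(length(p0) == 2, length(p1) == 2)
  for (p in list(p0, p1)) {
    if (p[1] < 1 || p[1] > nrow(m) || p[2] < 1 || p[2] > ncol(m)) {
      stop("line endpoints must lie inside the image", call. = FALSE)
    }
  }
  d <- sqrt(sum((p1 - p0)^2))
  n <- ceiling(d) + 1
  tt <- if (n == 1) 0 else seq(0, 1, length.out = n)
  r <- p0[1] + tt * (p1[1] - p0[1])
  cc <- p0[2] + tt * (p1[2] - p0[2])
  r0 <- pmin(floor(r), nrow(m) - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(cc), ncol(m) - 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0
  fc <- cc - c0
  (1 - fr) * (1 - fc) * m[cbind(r0, c0)] +
    fr * (1 - fc) * m[cbind(r0 + 1L, c0)] +
    (1 - fr) * fc * m[cbind(r0, c0 + 1L)] +
    fr * fc * m[cbind(r0 + 1L, c0 + 1L)]
}
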