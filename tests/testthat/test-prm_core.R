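test_that("an exact match scores 1 at zero shift for any penalty weight", {
  cfg0 <- preprocess_config()
  refs <- c(lapply(demo_peak_sets(), make_reference, grid = ch_grid()),
            list(narrow = narrow_ref_raw()))
  for (raw in refs) {
    u <- preprocess_pixel(raw, cfg0)
    for (alpha in c(0, 1e-4, 4e-4, 0.1)) {
      r <- prm_score(u, u, prm_config(alpha = alpha))
      expect_equal(r$score, 1, tolerance = 1e-9)
      expect_identical(r$best_shift, 0)
    }
  }
})

test_that("a cleanly shifted copy recovers the closed form 1 - alpha k^2", {
  pcfg <- preprocess_config()
  raw <- narrow_ref_raw()
  ref <- preprocess_reference(raw, pcfg)
  cfg <- prm_config(alpha = 1e-4)
  ks <- -30:30
  scores <- numeric(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    pix <- preprocess_pixel(shifted_copy(raw, k), pcfg)
    r <- prm_score(pix, ref, cfg)
    expect_equal(r$score, 1 - 1e-4 * k^2, tolerance = 1e-9)
    expect_identical(r$best_shift, as.numeric(k))
    scores[i] <- r$score
  }
  # strictly decreasing in |k|
  pos <- scores[ks >= 0]
  expect_true(all(diff(pos) < 0))
  neg <- scores[ks <= 0]
  expect_true(all(diff(neg) > 0))

  # with alpha = 0 the shift goes unpenalized
  r0 <- prm_score(preprocess_pixel(shifted_copy(raw, 17), pcfg), ref,
                  prm_config(alpha = 0))
  expect_equal(r0$score, 1, tolerance = 1e-9)
})

test_that("scores stay within [0, 1] and are monotone in the penalty weight", {
  pcfg <- preprocess_config()
  ref <- preprocess_reference(narrow_ref_raw(), pcfg)
  withr::with_seed(11, {
    for (rep in 1:20) {
      y <- runif(451)
      u <- preprocess_pixel(raman_spectrum(ch_grid(), y), pcfg)
      alphas <- c(0, 0.25e-4, 1e-4, 4e-4, 1e-2, 1)
      sc <- vapply(alphas, function(a) prm_score(u, ref, prm_config(alpha = a))$score,
                   numeric(1))
      expect_true(all(sc >= 0 & sc <= 1))
      expect_true(all(diff(sc) <= 1e-12))  # non-increasing in alpha
      # at very large alpha only the unshifted term survives
      expect_equal(sc[length(sc)],
                   min(max(sum(u$intensity * ref$intensity), 0), 1),
                   tolerance = 1e-12)
    }
  })
})

test_that("the per-shift trace is exact and its maximum is the score", {
  pcfg <- preprocess_config()
  raw <- narrow_ref_raw()
  ref <- preprocess_reference(raw, pcfg)
  pix <- preprocess_pixel(shifted_copy(raw, 9), pcfg)
  cfg <- prm_config(alpha = 1e-4, max_shift = 15)
  r <- prm_score(pix, ref, cfg, return_trace = TRUE)
  expect_length(r$per_shift_scores, 31)
  for (k in c(-15, -3, 0, 9, 15)) {
    n <- length(ref$intensity)
    shifted <- if (k == 0) ref$intensity
      else if (k > 0) c(rep(0, k), ref$intensity[1:(n - k)])
      else c(ref$intensity[(1 - k):n], rep(0, -k))
    expect_equal(unname(r$per_shift_scores[as.character(k)]),
                 sum(pix$intensity * shifted) - 1e-4 * k^2, tolerance = 1e-12)
  }
  expect_equal(r$score, max(r$per_shift_scores))
  expect_equal(r$best_shift, 9)
})

test_that("exact ties break to the smallest magnitude, then the negative shift", {
  # delta reference, two-delta pixel: offsets +1 and -1 give identical scores
  wn <- 2700:2710
  ref <- raman_spectrum(wn, c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0),
                        stage = "unit_norm")
  pix <- raman_spectrum(wn, c(0, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0) / sqrt(2),
                        stage = "unit_norm")
  r <- prm_score(pix, ref, prm_config(alpha = 0, max_shift = 3))
  expect_identical(r$best_shift, -1)
  expect_equal(r$score, 1 / sqrt(2), tolerance = 1e-12)
})

test_that("grid and stage preconditions are enforced", {
  pcfg <- preprocess_config()
  u <- preprocess_reference(narrow_ref_raw(), pcfg)
  other <- preprocess_reference(narrow_ref_raw(),
                                preprocess_config(grid_range = c(2700, 3100)))
  expect_error(prm_score(u, other), "same axis")
  expect_error(prm_score(narrow_ref_raw(), u), "unit_norm")
})

test_that("vectorized stack scoring equals the per-pixel per-shift loop oracle", {
  pcfg <- preprocess_config()
  cfg <- prm_config(alpha = 1e-4, max_shift = 30)
  stack <- random_stack(101)
  ref <- preprocess_reference(narrow_ref_raw(), pcfg)
  fast <- score_stack(stack, ref, pcfg, cfg)
  slow <- oracle_score_stack(stack, ref$intensity, ch_grid(), 1e-4, 30)
  expect_lt(max(abs(fast$scores - slow$scores)), 1e-12)
  expect_identical(fast$best_shift, slow$shifts)

  # chunked execution is bit-identical to a single pass
  chunked <- score_stack(stack, ref, pcfg, cfg, chunk_size = 16)
  expect_identical(chunked$scores, fast$scores)
  expect_identical(chunked$best_shift, fast$best_shift)
})

test_that("pixels that are affine copies of the reference all score 1", {
  pcfg <- preprocess_config()
  raw <- make_reference(list(c(1, 2850, 14), c(0.6, 2935, 20)), ch_grid())
  grid <- ch_grid()
  withr::with_seed(5, {
    a <- matrix(runif(36, 0.2, 4), 6, 6)
    b <- matrix(runif(36, -2, 8), 6, 6)
  })
  data <- array(0, dim = c(6, 6, length(grid)))
  for (i in 1:6) for (j in 1:6) data[i, j, ] <- a[i, j] * raw$intensity + b[i, j]
  stack <- hsi_stack(data, grid)
  img <- score_stack(stack, raw, pcfg)
  expect_true(all(abs(img$scores - 1) < 1e-9))
  expect_true(all(img$best_shift == 0))
})

test_that("degenerate pixels are masked with zero score, others still scored", {
  pcfg <- preprocess_config()
  raw <- narrow_ref_raw()
  grid <- ch_grid()
  data <- array(0, dim = c(2, 2, length(grid)))
  for (i in 1:2) for (j in 1:2) data[i, j, ] <- raw$intensity
  data[1, 2, ] <- 3  # constant pixel
  img <- score_stack(hsi_stack(data, grid), raw, pcfg)
  expect_true(img$mask[1, 2])
  expect_equal(img$scores[1, 2], 0)
  others <- cbind(c(1, 2, 2), c(1, 1, 2))
  expect_true(all(!img$mask[others]))
  expect_true(all(abs(img$scores[!img$mask] - 1) < 1e-9))
})

test_that("multi-reference scoring reuses one preprocessing pass per pixel", {
  pcfg <- preprocess_config()
  lib <- demo_library(pcfg)
  stack <- random_stack(202, nr = 5, nc = 7)
  reset_prm_counters()
  out <- score_stack_multi(stack, lib, pcfg)
  expect_named(out, names(lib$entries))
  expect_equal(prm_counters()$preprocessed_pixels, 5 * 7)

  # two identical references produce identical score images
  lib2 <- reference_library(list(a = lib$entries$tag_like,
                                 b = lib$entries$tag_like))
  out2 <- score_stack_multi(stack, lib2, pcfg)
  expect_identical(out2$a$scores, out2$b$scores)
})

test_that("the argmax reference recovers a pure two-phase partition exactly", {
  pcfg <- preprocess_config()
  lib <- demo_library(pcfg)
  sim <- make_stack(sim_spec(seed = 3, noise_sd = 0, jitter_sd = 0,
                             layout = "two_phase"), lib)
  out <- score_stack_multi(sim$stack, lib, pcfg)
  sc <- vapply(out, function(im) im$scores,
               matrix(0, dim(sim$stack)[1], dim(sim$stack)[2]))
  arg <- apply(sc, c(1, 2), which.max)
  dimnames(arg) <- NULL
  truth <- ifelse(sim$weights[, , 1] == 1, 1L, 2L)
  dimnames(truth) <- NULL
  expect_identical(arg, truth)
})
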