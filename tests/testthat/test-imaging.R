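mk_score <- function(m, mask = NULL, name = "ref") {
  score_image(m, m * 0, mask, reference_name = name)
}

test_that("ratio images follow the masking contract", {
  A <- matrix(runif(16, 0.2, 0.9), 4, 4)
  r <- ratio_image(mk_score(A), mk_score(A))
  expect_true(all(r$values[!r$mask] == 1))
  expect_true(all(!r$mask))

  num <- mk_score(matrix(0.9, 4, 4), name = "chol")
  den_m <- matrix(0.45, 4, 4)
  den_m[2, 2] <- 0
  den <- mk_score(den_m, name = "pe")
  r2 <- ratio_image(num, den, epsilon = 1e-6)
  expect_true(r2$mask[2, 2])
  expect_true(is.na(r2$values[2, 2]))
  expect_true(all(r2$values[!r2$mask] == 2))
  expect_equal(r2$numerator_name, "chol")

  # input masks propagate as a union
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE
  r3 <- ratio_image(mk_score(matrix(0.5, 4, 4), m), den)
  expect_true(r3$mask[1, 1] && r3$mask[2, 2])

  expect_error(ratio_image(mk_score(A), mk_score(matrix(1, 3, 3))), "shape")
})

test_that("threshold masks are monotone and split a two-phase image", {
  sc <- matrix(c(rep(0.9, 8), rep(0.3, 8)), 4, 4)
  img <- mk_score(sc)
  expect_true(all(threshold_mask(img, 0)))
  expect_true(!any(threshold_mask(img, 1 + 1e-9)))
  mid <- threshold_mask(img, 0.6)
  expect_identical(mid, sc >= 0.6)
  expect_equal(sum(mid), 8)

  # monotone: raising t can only shrink the mask
  ts <- seq(0, 1, by = 0.1)
  for (i in seq_along(ts)[-1]) {
    expect_true(all(threshold_mask(img, ts[i]) <= threshold_mask(img, ts[i - 1])))
  }

  # masked pixels are never selected
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE
  img2 <- mk_score(sc, m)
  expect_false(threshold_mask(img2, 0)[1, 1])
})

test_that("top-percentile extraction selects and averages the right pixels", {
  pcfg <- preprocess_config()
  lib <- demo_library(pcfg)
  sim <- make_stack(sim_spec(seed = 6, noise_sd = 0, jitter_sd = 0,
                             layout = "two_phase"), lib)
  img <- score_stack(sim$stack, lib$entries$tag_like, pcfg)

  # the pure-reference region dominates the top decile; its mean spectrum
  # still matches the reference almost perfectly
  ts <- top_percentile_spectra(sim$stack, img, 90, pcfg)
  sc <- prm_score(preprocess_pixel(ts$mean_spectrum, pcfg),
                  lib$entries$tag_like)
  expect_gte(sc$score, 0.999)

  # uniform score map: percentile degenerates to the mean over all pixels
  uni <- mk_score(matrix(0.7, dim(sim$stack)[1], dim(sim$stack)[2]))
  tu <- top_percentile_spectra(sim$stack, uni, 90, pcfg)
  expect_equal(tu$n_selected, prod(dim(sim$stack)[1:2]))

  # a strictly top pixel is returned alone with zero deviation
  one <- matrix(0.5, dim(sim$stack)[1], dim(sim$stack)[2])
  one[3, 3] <- 0.99
  t1 <- top_percentile_spectra(sim$stack, mk_score(one), 99.9, pcfg)
  expect_equal(t1$n_selected, 1)
  expect_true(all(t1$sd == 0))

  # all-masked selection errors
  allm <- mk_score(one, matrix(TRUE, nrow(one), ncol(one)))
  expect_error(top_percentile_spectra(sim$stack, allm, 90, pcfg), "masked")
})

test_that("channel merging is additive with fixed scaling", {
  a <- matrix(c(rep(0.8, 8), rep(0, 8)), 4, 4)
  b <- matrix(c(rep(0, 8), rep(0.6, 8)), 4, 4)

  # single channel: composite is the score times the colour
  g <- merge_channels(list(mk_score(a)), list(c(1, 1, 1)))
  for (ch in 1:3) expect_equal(g[, , ch], a)

  # disjoint supports never mix colours
  m <- merge_channels(list(mk_score(a), mk_score(b)), c("red", "green"))
  expect_true(!any(m[, , 1] > 0 & m[, , 2] > 0))
  expect_equal(attr(m, "n_clipped"), 0)

  # identical channels in red + green make yellow, never blue
  y <- merge_channels(list(mk_score(a), mk_score(a)), c("red", "green"))
  expect_equal(y[, , 1], y[, , 2])
  expect_true(all(y[, , 3] == 0))

  # clipping at 1 is recorded
  cl <- merge_channels(list(mk_score(a), mk_score(a)), c("white", "white"))
  expect_gt(attr(cl, "n_clipped"), 0)
  expect_lte(max(cl), 1)

  expect_error(merge_channels(list(mk_score(a), mk_score(matrix(0, 2, 2))),
                              c("red", "green")), "shape")
})

test_that("image agreement matches its definition and a frozen external value", {
  i <- matrix(rep(1:16, 16), 16, 16)
  j <- t(i)
  a <- (sin(0.7 * i) + cos(1.3 * j) + 2) / 4
  b <- a + 0.1 * sin(0.5 * i * j) / 4

  # identity
  ag <- image_agreement(a, a)
  expect_equal(ag$similarity_index, 1)
  expect_equal(ag$nmse, 0)

  # zero image against any nonzero target has unit NMSE
  expect_equal(image_agreement(matrix(0, 16, 16), a)$nmse, 1)

  # frozen oracle value computed once with scikit-image's
  # structural_similarity (7x7 uniform windows, data_range 1) on this exact
  # fixture after the same joint [0,1] scaling
  r <- image_agreement(a, b)
  expect_equal(r$similarity_index, 0.9972301755778301, tolerance = 1e-12)
  expect_equal(r$nmse, 0.0009565458536661152, tolerance = 1e-12)

  # monotone degradation with noise
  withr::with_seed(21, {
    n1 <- a + matrix(rnorm(256, 0, 0.02), 16, 16)
    n2 <- a + matrix(rnorm(256, 0, 0.2), 16, 16)
    ind <- matrix(runif(256), 16, 16)
  })
  s1 <- image_agreement(n1, a)$similarity_index
  s2 <- image_agreement(n2, a)$similarity_index
  s_ind <- image_agreement(ind, a)$similarity_index
  expect_true(s2 < s1 && s1 < 1)
  expect_gt(s1, s_ind)

  expect_error(image_agreement(matrix(0, 16, 16), matrix(0, 16, 16)), "nmse")
  expect_error(image_agreement(a, matrix(1, 4, 4)), "shape")
})

test_that("line profiles sample bilinearly at unit spacing", {
  const <- matrix(3.5, 10, 10)
  p <- line_profile(const, c(2, 1), c(2, 10))
  expect_length(p, 10)  # ceil(9) + 1
  expect_true(all(p == 3.5))

  # a plane is reproduced exactly under bilinear interpolation
  plane <- outer(1:10, 1:10, function(r, cc) 2 * r + 3 * cc)
  d <- sqrt(8^2 + 7^2)
  prof <- line_profile(plane, c(1, 2), c(9, 9))
  expect_length(prof, ceiling(d) + 1)
  tt <- seq(0, 1, length.out = length(prof))
  expect_equal(prof, 2 * (1 + tt * 8) + 3 * (2 + tt * 7), tolerance = 1e-12)

  expect_error(line_profile(const, c(0, 1), c(5, 5)), "inside")
})
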