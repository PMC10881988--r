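# shared fixture builders and an independent scoring oracle

ch_grid <- function() seq(2700, 3150, by = 1)

# narrow two-band reference: its shifted autocorrelation decays faster than
# the default quadratic penalty relaxes, so the shift closed form is exact
narrow_ref_raw <- function() {
  make_reference(list(c(1, 2850, 3), c(0.7, 2935, 3)), ch_grid(),
                 label = "narrow")
}

# copy of a raw spectrum slid by +k cm^-1 (edge values extended)
shifted_copy <- function(s, k) {
  raman_spectrum(s$wavenumber,
                 stats::approx(s$wavenumber, s$intensity,
                               xout = s$wavenumber - k, rule = 2)$y,
                 stage = "raw", label = s$label)
}

penalty_lib <- function(pcfg = preprocess_config()) {
  ps <- penalty_demo_peak_sets()
  build_library(list(phase_a = make_reference(ps$phase_a, ch_grid(), label = "phase_a"),
                     phase_b = make_reference(ps$phase_b, ch_grid(), label = "phase_b")),
                pcfg)
}

# ---- independent scoring oracle: plain per-pixel, per-shift loops ---------

oracle_preprocess <- function(y, axis, grid) {
  inside <- grid >= min(axis) & grid <= max(axis)
  v <- numeric(length(grid))
  v[inside] <- stats::approx(axis, y, xout = grid[inside])$y
  rng <- range(v)
  if (rng[2] <= rng[1]) return(NULL)  # degenerate
  v <- (v - rng[1]) / (rng[2] - rng[1])
  v / sqrt(sum(v^2))
}

oracle_shift <- function(v, k) {
  n <- length(v)
  if (k == 0) return(v)
  if (abs(k) >= n) return(numeric(n))
  if (k > 0) c(rep(0, k), v[1:(n - k)]) else c(v[(1 - k):n], rep(0, -k))
}

oracle_prm <- function(u, v, alpha, max_shift) {
  ks <- -max_shift:max_shift
  ks <- ks[order(abs(ks), ks)]  # tie-break order
  best <- -Inf
  best_k <- 0
  for (k in ks) {
    s <- sum(u * oracle_shift(v, k)) - alpha * k^2
    if (s > best) {
      best <- s
      best_k <- k
    }
  }
  list(score = min(max(best, 0), 1), best_shift = best_k)
}

oracle_score_stack <- function(stack, ref_vec, grid, alpha, max_shift) {
  d <- dim(stack$data)
  scores <- matrix(0, d[1], d[2])
  shifts <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      u <- oracle_preprocess(stack$data[i, j, ], stack$wavenumber, grid)
      if (is.null(u)) next
      r <- oracle_prm(u, ref_vec, alpha, max_shift)
      scores[i, j] <- r$score
      shifts[i, j] <- r$best_shift
    }
  }
  list(scores = scores, shifts = shifts)
}

# seeded random stack on the acquired band axis
random_stack <- function(seed, nr = 8, nc = 8, nb = 75) {
  withr::with_seed(seed, {
    axis <- seq(2700, by = 6, length.out = nb)
    hsi_stack(array(stats::runif(nr * nc * nb), dim = c(nr, nc, nb)), axis)
  })
}
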