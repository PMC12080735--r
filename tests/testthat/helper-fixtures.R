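# Shared fixtures and independent oracles, built in code at test time.

noise_free_config <- function(...) {
  cohort_config(n_subjects = 1, noise_sd = 0, seed = 1, ...)
}

# A small random-but-smooth profile: double bump plus low-order harmonics,
# strictly peaked inside the ST/IT windows.
random_bump_profile <- function(cfg = noise_free_config(),
                                st = runif(1, 40, 100),
                                it = runif(1, 255, 330)) {
  p <- generate_profile(cfg, st, it)
  wig <- 2 * sin(p$angle_deg * pi / 180 * runif(1, 1, 3) + runif(1, 0, 6))
  p$thickness_um <- p$thickness_um + wig
  list(profile = p, st = st, it = it)
}

# Brute-force sample-level rotation of a map about its ONH centre by
# `delta_deg` (CCW in the y-up frame), via bilinear pull-back. Independent
# oracle for align_foa().
rotate_map_oracle <- function(map, delta_deg) {
  g <- map$grid
  n <- nrow(g)
  cx <- map$onh_center[1]; cy <- map$onh_center[2]
  th <- delta_deg * pi / 180
  out <- matrix(0, n, n)
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  dx <- xs - cx
  dy <- ys - cy
  # rotating content by +delta pulls from -delta; CCW y-up == CW y-down
  sx <- cx + dx * cos(th) - dy * sin(th)
  sy <- cy + dx * sin(th) + dy * cos(th)
  ok <- sx >= 1 & sx <= n & sy >= 1 & sy <= n
  vals <- rnfltnorm:::bilinear_at(g, pmin(pmax(as.vector(sx), 1), n),
                                  pmin(pmax(as.vector(sy), 1), n))
  out[ok] <- vals[ok]
  map$grid <- out
  map
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
wilcoxon_enum_oracle <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- as.matrix(signs) %*% r
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

expect_profiles_equal <- function(a, b, tol = 1e-8) {
  expect_equal(a$thickness_um, b$thickness_um, tolerance = tol)
}
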