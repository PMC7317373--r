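# Shared fixtures: small phantom configurations and geometric masks built in
# code, so tests stay fast and the repository stays text-only.

# compact phantom: 128 px grid, shorter series, geometry scaled down
small_config <- function(...) {
  phantom_config(image_size = 128, n_frames = 40,
                 lv_center_range = c(-4, 4),
                 lv_pool_radius_range = c(10, 13),
                 myo_thickness_range = c(5, 7),
                 aif_params = list(
                   rest = list(t0 = 8, alpha = 2.5, beta = 2.5, scale = 5),
                   stress = list(t0 = 6, alpha = 2.0, beta = 2.0, scale = 5)),
                 ...)
}

# deterministic geometry: exact radii, centred
exact_config <- function(image_size = 256, r_pool = 20, thickness = 10, ...) {
  phantom_config(image_size = image_size,
                 lv_center_range = c(0, 0),
                 lv_pool_radius_range = c(r_pool, r_pool),
                 myo_thickness_range = c(thickness, thickness), ...)
}

disk_mask <- function(n, ctr, r) {
  rows <- matrix(0:(n - 1), n, n)
  cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
  matrix(as.integer((rows - ctr[1])^2 + (cols - ctr[2])^2 <= r^2), n, n)
}

annulus_mask <- function(n, ctr, r_in, r_out) {
  matrix(as.integer(disk_mask(n, ctr, r_out) & !disk_mask(n, ctr, r_in)),
         n, n)
}

# annulus with an arc removed (degrees), for closed-loop QC failures
broken_annulus <- function(n, ctr, r_in, r_out, arc_from = 0, arc_to = 10) {
  m <- annulus_mask(n, ctr, r_in, r_out)
  rows <- matrix(0:(n - 1), n, n)
  cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
  ang <- (atan2(-(rows - ctr[1]), cols - ctr[2]) * 180 / pi) %% 360
  m[ang >= arc_from & ang <= arc_to] <- 0L
  m
}

# reference RK4 integration of the 2CXM ODEs with linear AIF interpolation;
# independent of the package's convolution solver
rk4_2cxm <- function(params, ca, times, substeps = 40) {
  Fp <- params$Fp / 60; PS <- params$PS / 60
  vp <- params$vp; ve <- params$ve
  f <- function(tt, u) {
    cai <- approx(times, ca, tt, rule = 2)$y
    c((Fp * (cai - u[1]) + PS * (u[2] - u[1])) / vp,
      PS * (u[1] - u[2]) / ve)
  }
  u <- c(0, 0)
  out <- numeric(length(times))
  for (i in 1:(length(times) - 1)) {
    h <- (times[i + 1] - times[i]) / substeps
    tt <- times[i]
    for (s in seq_len(substeps)) {
      k1 <- f(tt, u); k2 <- f(tt + h / 2, u + h / 2 * k1)
      k3 <- f(tt + h / 2, u + h / 2 * k2); k4 <- f(tt + h, u + h * k3)
      u <- u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tt <- tt + h
    }
    out[i + 1] <- vp * u[1] + ve * u[2]
  }
  out
}

# brute-force Dice by explicit pixel counting (independent of dsc())
dsc_bruteforce <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    ai <- a[i] != 0; bi <- b[i] != 0
    na <- na + ai; nb <- nb + bi
    inter <- inter + (ai && bi)
  }
  if (na + nb == 0) 1 else 2 * inter / (na + nb)
}

# exhaustive-search landmark oracle: the integer landmark whose exact action
# map disagrees least with `map`, searched in a window around `centre`
landmark_search_oracle <- function(map, centre, radius = 4) {
  best <- NULL; best_err <- Inf
  for (r in (round(centre[1]) - radius):(round(centre[1]) + radius)) {
    for (c in (round(centre[2]) - radius):(round(centre[2]) + radius)) {
      if (r < 0 || r > nrow(map) - 1 || c < 0 || c > ncol(map) - 1) next
      cand <- build_action_map(dim(map), c(r, c))
      err <- sum(cand != map)
      if (err < best_err) { best_err <- err; best <- c(r, c) }
    }
  }
  list(point = best, disagreement = best_err)
}
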