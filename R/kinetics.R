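## Tracer-kinetic quantification: two-compartment exchange model (2CXM),
## signal-to-concentration conversion, AIF extraction by region growing,
## AHA 16-segment division and per-segment MBF reporting.
##
## Units: plasma flow Fp and permeability-surface-area product PS are carried
## in mL/min/mL externally and converted to s^-1 internally by the single
## constant 1/60; volume fractions vp, ve are dimensionless.

#' Construct a 2CXM parameter set
#'
#' @param Fp plasma flow in mL/min/mL (equals myocardial blood flow, MBF).
#' @param vp plasma volume fraction.
#' @param PS permeability-surface-area product in mL/min/mL.
#' @param ve interstitial (extravascular extracellular) volume fraction.
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(Fp, vp, PS, ve) {
  p <- c(Fp = Fp, vp = vp, PS = PS, ve = ve)
  if (any(!is.finite(p)) || any(p < 0))
    stop("kinetic parameters must be finite and non-negative")
  if (vp + ve > 1 + 1e-9)
    stop("vp + ve must not exceed 1")
  structure(as.list(p), class = "kinetic_params")
}

#' Construct a concentration curve
#'
#' @param times strictly increasing sample times in seconds.
#' @param values finite concentrations (arbitrary linear units).
#' @return object of class `concentration_curve`.
#' @export
concentration_curve <- function(times, values) {
  stopifnot(length(times) == length(values), all(diff(times) > 0),
            all(is.finite(values)))
  structure(list(times = as.double(times), values = as.double(values)),
            class = "concentration_curve")
}

## Bi-exponential impulse response of the 2CXM: h(t) = sum_j c_j exp(-k_j t)
## (k in s^-1, amplitudes in s^-1 so that Ct = h (*) Ca is dimensionless in
## Ca's units). Degenerate volumes handled by their analytic limits.
cxm_impulse <- function(params) {
  Fp <- params$Fp / 60; PS <- params$PS / 60
  vp <- params$vp; ve <- params$ve
  if (Fp == 0) return(list(c = 0, k = 0))
  if (vp == 0) {
    if (PS == 0 || ve == 0) return(list(c = 0, k = 0))
    kappa <- Fp * PS / (Fp + PS)
    return(list(c = kappa, k = kappa / ve))
  }
  if (ve == 0 || PS == 0) {
    return(list(c = Fp, k = Fp / vp))
  }
  A <- matrix(c(-(Fp + PS) / vp, PS / ve, PS / vp, -PS / ve), 2, 2)
  eg <- eigen(A)
  winv <- c(vp, ve) %*% eg$vectors          # row vector
  g <- solve(eg$vectors, c(Fp / vp, 0))
  list(c = as.double(Re(winv) * Re(g)), k = as.double(-Re(eg$values)))
}

## Exact convolution of exp(-k t) with a piecewise-linear input on `times`.
## Recursive exponential integrator; k = 0 reduces to the trapezoidal
## running integral.
conv_exp_pwlinear <- function(k, ca, times) {
  n <- length(times)
  y <- numeric(n)
  if (n < 2) return(y)
  for (i in 1:(n - 1)) {
    dt <- times[i + 1] - times[i]
    m <- (ca[i + 1] - ca[i]) / dt
    if (k * dt > 1e-12) {
      E <- exp(-k * dt)
      I0 <- (1 - E) / k
      y[i + 1] <- E * y[i] + ca[i] * I0 + m * (dt - I0) / k
    } else {
      y[i + 1] <- y[i] + ca[i] * dt + m * dt^2 / 2
    }
  }
  y
}

#' Solve the two-compartment exchange model forward problem
#'
#' Tissue concentration for the 2CXM
#' \deqn{v_p C_p' = F_p (C_a - C_p) + PS (C_e - C_p), \quad
#'       v_e C_e' = PS (C_p - C_e), \quad C_t = v_p C_p + v_e C_e,}
#' computed as the convolution of the arterial input with the model's
#' bi-exponential impulse response, exact for a piecewise-linear AIF.
#' Degenerate volumes (`vp == 0`, `ve == 0`, `PS == 0`, `Fp == 0`) use their
#' analytic limits.
#'
#' @param params a [kinetic_params()] (Fp and PS in mL/min/mL).
#' @param aif a [concentration_curve()] sampled on `times`.
#' @param times sample times in seconds; defaults to `aif$times`.
#' @return a [concentration_curve()] of tissue concentration.
#' @export
solve_2cxm <- function(params, aif, times = aif$times) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!isTRUE(all.equal(times, aif$times)))
    stop("aif must be sampled on `times`")
  ir <- cxm_impulse(params)
  ct <- numeric(length(times))
  for (j in seq_along(ir$c)) {
    if (ir$c[j] == 0) next
    ct <- ct + ir$c[j] * conv_exp_pwlinear(ir$k[j], aif$values, times)
  }
  concentration_curve(times, ct)
}

## Fast path used by the phantom and voxelwise fitting: tissue curves for many
## parameter sets against one AIF. `pars` is a 4-column matrix (Fp, vp, PS, ve).
solve_2cxm_many <- function(pars, ca, times) {
  n <- nrow(pars)
  out <- matrix(0, length(times), n)
  for (i in seq_len(n)) {
    p <- kinetic_params(pars[i, 1], pars[i, 2], pars[i, 3], pars[i, 4])
    ir <- cxm_impulse(p)
    for (j in seq_along(ir$c)) {
      if (ir$c[j] == 0) next
      out[, i] <- out[, i] + ir$c[j] * conv_exp_pwlinear(ir$k[j], ca, times)
    }
  }
  out
}

#' Convert a signal curve to a concentration curve
#'
#' Linear signal model \eqn{S(t) = S_0 (1 + \gamma C(t))}, inverted as
#' \eqn{C(t) = (S(t) - S_0) / (\gamma S_0)} with the baseline \eqn{S_0} the
#' mean of the first `baseline_frames` samples. This is the phantom's exact
#' inverse; for clinical saturation-recovery data it is a stand-in for the
#' sequence-specific conversion.
#'
#' @param signal numeric vector of signal intensities.
#' @param times sample times in seconds.
#' @param baseline_frames number of pre-contrast frames averaged into S0.
#' @param gamma signal gain per unit concentration.
#' @return a [concentration_curve()].
#' @export
signal_to_conc <- function(signal, times = seq_along(signal) - 1,
                           baseline_frames = 5, gamma = 1.0) {
  stopifnot(baseline_frames >= 1, baseline_frames <= length(signal))
  s0 <- mean(signal[seq_len(baseline_frames)])
  if (s0 <= 0) stop("baseline signal S0 must be positive")
  concentration_curve(times, (signal - s0) / (gamma * s0))
}

#' Interior (LV cavity) enclosed by a myocardial mask
#'
#' The union of 4-connected background components that do not touch the image
#' border: for a closed-loop myocardium this is the endocardial interior used
#' to seed AIF extraction.
#'
#' @param myo_mask binary matrix.
#' @return binary matrix of the enclosed interior.
#' @export
interior_from_mask <- function(myo_mask) {
  m <- matrix(as.integer(myo_mask != 0), nrow(myo_mask), ncol(myo_mask))
  bg <- cc_label(1L - m, 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- setdiff(border_labels, 0L)
  interior <- bg > 0 & !(bg %in% border_labels)
  matrix(as.integer(interior), nrow(m), ncol(m))
}

#' Extract the arterial input function by region growing
#'
#' Seeds at the brightest voxel of the peak frame inside the endocardial
#' interior and grows a 4-connected region admitting neighbours whose
#' peak-frame signal is at least `grow_threshold` times the seed signal,
#' restricted to the interior. The AIF is the spatial mean signal of the
#' region per frame, converted to concentration with [signal_to_conc()].
#'
#' @param series a [perfusion_series()] (cropped to the LV region).
#' @param endo_interior binary matrix, e.g. from [interior_from_mask()].
#' @param peak 0-based index of the peak LV enhancement frame.
#' @param grow_threshold admission threshold as a fraction of the seed signal.
#' @param baseline_frames,gamma passed to [signal_to_conc()].
#' @return list with `aif` (a [concentration_curve()]), `region` (binary
#'   matrix), `seed` (0-based (row, col)) and `flag` (warning string or NA).
#' @export
extract_aif <- function(series, endo_interior, peak, grow_threshold = 0.9,
                        baseline_frames = 5, gamma = 1.0) {
  stopifnot(peak >= 0, peak < n_frames(series))
  interior <- endo_interior != 0
  if (!any(interior)) stop("endocardial interior is empty")
  pf <- series$frames[, , peak + 1]
  pf_in <- ifelse(interior, pf, -Inf)
  seed_idx <- which.max(pf_in)
  seed <- c((seed_idx - 1) %% nrow(pf), (seed_idx - 1) %/% nrow(pf))
  thr <- grow_threshold * pf[seed_idx]
  admissible <- matrix(as.integer(interior & pf >= thr), nrow(pf), ncol(pf))
  lab <- cc_label(admissible, 4L)
  region <- lab == lab[seed_idx]
  flag <- NA_character_
  if (sum(region) < 5) flag <- "AIF region smaller than 5 voxels"
  sig <- apply(series$frames, 3, function(fr) mean(fr[region]))
  aif <- signal_to_conc(sig, series$frame_times, baseline_frames, gamma)
  list(aif = aif, region = matrix(as.integer(region), nrow(pf), ncol(pf)),
       seed = seed, flag = flag)
}

## ---- model fitting -------------------------------------------------------

.fit_bounds <- list(lower = c(Fp = 0, vp = 0, PS = 0, ve = 0),
                    upper = c(Fp = 10, vp = 0.5, PS = 5, ve = 0.8))

.fit_objective <- function(theta, ct, ca, times, prior = NULL) {
  pred <- cxm_tissue_cpp(theta[1], theta[2], theta[3], theta[4], ca, times)
  pen <- max(0, theta[2] + theta[4] - 1)^2 * 1e4
  if (!is.null(prior)) {
    z <- (theta - prior$mu) / prior$sd
    pen <- pen + prior$lambda * sum(z[is.finite(z)]^2)
  }
  sum((pred - ct)^2) + pen
}

#' Physiologic ridge prior for 2CXM fitting
#'
#' Quadratic penalty toward physiologic values, added to the least-squares
#' objective as `lambda * sum(((theta - mu) / sd)^2)` (infinite `sd` leaves a
#' parameter unpenalised). At first-pass temporal resolution the 2CXM is
#' weakly identifiable: without regularisation, noisy curves are often fit
#' best by a degenerate corner (`Fp` at its bound with a vanishing plasma
#' volume). The default penalises only the volume fractions, anchoring `vp`
#' and `ve` near myocardial values while leaving `Fp` and `PS` free.
#'
#' @param mu prior means (Fp, vp, PS, ve).
#' @param sd prior scales; `Inf` disables the penalty for that parameter.
#' @param lambda global penalty weight (concentration-squared units).
#' @return list usable as the `prior` argument of [fit_2cxm()].
#' @export
cxm_prior <- function(mu = c(Fp = 1.5, vp = 0.06, PS = 1.0, ve = 0.2),
                      sd = c(Fp = Inf, vp = 0.05, PS = Inf, ve = 0.15),
                      lambda = 0.003) {
  list(mu = unname(mu), sd = unname(sd), lambda = lambda)
}

#' Fit the 2CXM to a tissue concentration curve
#'
#' Bounded nonlinear least squares (box constraints Fp in [0, 10] mL/min/mL,
#' vp in [0, 0.5], PS in [0, 5] mL/min/mL, ve in [0, 0.8], soft constraint
#' vp + ve <= 1) with multi-start from points along the diagonal of the
#' parameter box.
#'
#' @param tissue,aif [concentration_curve()]s on a common time grid.
#' @param n_starts number of multi-start points (default 5).
#' @param start optional explicit starting [kinetic_params()]; replaces the
#'   grid when given.
#' @param prior optional [cxm_prior()] ridge penalty; NULL (default) is plain
#'   least squares.
#' @return list with `params` ([kinetic_params()]), `residual_norm`,
#'   `converged` flag, and `objective`.
#' @export
fit_2cxm <- function(tissue, aif, n_starts = 5, start = NULL, prior = NULL) {
  if (!isTRUE(all.equal(tissue$times, aif$times)))
    stop("tissue and aif must share a time grid")
  if (any(!is.finite(tissue$values)) || any(!is.finite(aif$values)))
    stop("non-finite input curves")
  lo <- .fit_bounds$lower; hi <- .fit_bounds$upper
  starts <- if (!is.null(start)) {
    matrix(unlist(start[c("Fp", "vp", "PS", "ve")]), 1)
  } else {
    fr <- seq(0.1, 0.9, length.out = n_starts)
    t(vapply(fr, function(f) lo + f * (hi - lo), numeric(4)))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      nlminb(starts[i, ], .fit_objective, lower = lo, upper = hi,
             ct = tissue$values, ca = aif$values, times = tissue$times,
             prior = prior, control = list(iter.max = 400, eval.max = 600)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  th <- pmin(pmax(best$par, lo), hi)
  if (th[2] + th[4] > 1) th[4] <- 1 - th[2]   # clamp soft constraint at return
  list(params = kinetic_params(th[1], th[2], th[3], th[4]),
       residual_norm = sqrt(best$objective),
       converged = best$convergence == 0,
       objective = best$objective)
}

## Dictionary of precomputed model curves on a coarse parameter grid, used to
## initialise voxelwise fitting cheaply.
fit_dictionary <- function(aif, times, n_per_axis = 5) {
  lo <- .fit_bounds$lower; hi <- .fit_bounds$upper
  axes <- lapply(1:4, function(j)
    seq(lo[j] + (hi[j] - lo[j]) * 0.05, hi[j] - (hi[j] - lo[j]) * 0.05,
        length.out = n_per_axis))
  grid <- as.matrix(expand.grid(axes))
  grid <- grid[grid[, 2] + grid[, 4] <= 1, , drop = FALSE]
  curves <- solve_2cxm_many(grid, aif$values, times)
  list(grid = grid, curves = curves)
}

#' Voxelwise 2CXM fitting over a masked image series
#'
#' Fits every voxel of `mask` by nonlinear least squares, initialised from the
#' best-matching entry of a precomputed coarse-grid curve dictionary (single
#' local refinement per voxel; use [fit_2cxm()] directly for the full
#' multi-start treatment of individual curves).
#'
#' @param conc array `[H, W, T]` of tissue concentrations.
#' @param aif a [concentration_curve()].
#' @param mask binary matrix of voxels to fit.
#' @param na_at_bounds flag fits whose Fp lands on the upper box bound as NA:
#'   in practice these are voxels whose curve is dominated by blood-pool
#'   partial volume, not tissue, and they would otherwise distort segment
#'   means.
#' @return list of parameter maps `Fp`, `vp`, `PS`, `ve` (matrices, NA outside
#'   the mask) plus `residual_norm` map.
#' @export
fit_2cxm_map <- function(conc, aif, mask, na_at_bounds = TRUE,
                         prior = NULL) {
  H <- dim(conc)[1]; W <- dim(conc)[2]
  times <- aif$times
  stopifnot(dim(conc)[3] == length(times))
  dict <- fit_dictionary(aif, times)
  idx <- which(mask != 0)
  maps <- replicate(5, matrix(NA_real_, H, W), simplify = FALSE)
  names(maps) <- c("Fp", "vp", "PS", "ve", "residual_norm")
  cmat <- matrix(conc, H * W, length(times))
  lo <- .fit_bounds$lower; hi <- .fit_bounds$upper
  for (v in idx) {
    ct <- cmat[v, ]
    sse0 <- colSums((dict$curves - ct)^2)
    th0 <- dict$grid[which.min(sse0), ]
    fit <- tryCatch(
      nlminb(th0, .fit_objective, lower = lo, upper = hi,
             ct = ct, ca = aif$values, times = times, prior = prior,
             control = list(iter.max = 200, eval.max = 300)),
      error = function(e) list(par = th0, objective = min(sse0)))
    fp <- fit$par[1]
    if (na_at_bounds && fp >= 0.999 * hi[1]) fp <- NA_real_
    maps$Fp[v] <- fp; maps$vp[v] <- fit$par[2]
    maps$PS[v] <- fit$par[3]; maps$ve[v] <- fit$par[4]
    maps$residual_norm[v] <- sqrt(fit$objective)
  }
  maps
}

## ---- AHA segments --------------------------------------------------------

.wrap360 <- function(a) ((a %% 360) + 360) %% 360

## angle of pixels about a centre, degrees, counterclockwise as displayed
## (x = col, y = -row), in [0, 360)
.pixel_angle <- function(rows, cols, centre) {
  .wrap360(atan2(-(rows - centre[1]), cols - centre[2]) * 180 / pi)
}

#' Divide a myocardial mask into AHA segments
#'
#' Angles are measured about the mask centroid; six 60-degree sectors for
#' basal (segments 1-6) and mid (7-12) slices and four 90-degree sectors for
#' the apical slice (13-16). Sector 1 (respectively 7, 13) starts at the
#' anterior RV insertion point and sectors proceed toward the inferior
#' insertion point through the septum. Labels partition the mask exactly.
#'
#' @param myo_mask binary matrix.
#' @param insertion_points list with `anterior` and `inferior` 0-based
#'   (row, col) points.
#' @param slice_level "basal", "mid" or "apical".
#' @return integer matrix of segment labels (0 outside the mask).
#' @export
aha_divide <- function(myo_mask, insertion_points,
                       slice_level = c("basal", "mid", "apical")) {
  slice_level <- match.arg(slice_level)
  idx <- which(myo_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty myocardial mask")
  centre <- c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)   # 0-based centroid
  pa <- insertion_points$anterior; pi_ <- insertion_points$inferior
  if (all(pa == pi_)) stop("insertion points must be distinct")
  th_a <- .pixel_angle(pa[1], pa[2], centre)
  th_i <- .pixel_angle(pi_[1], pi_[2], centre)
  delta <- .wrap360(th_i - th_a)
  dir <- if (delta <= 180) 1 else -1        # rotate through the septum
  n_sect <- if (slice_level == "apical") 4L else 6L
  width <- 360 / n_sect
  offset <- switch(slice_level, basal = 0L, mid = 6L, apical = 12L)
  th <- .pixel_angle(idx[, 1] - 1, idx[, 2] - 1, centre)
  rel <- .wrap360((th - th_a) * dir)
  sect <- pmin(floor(rel / width), n_sect - 1L) + 1L
  labels <- matrix(0L, nrow(myo_mask), ncol(myo_mask))
  labels[idx] <- as.integer(offset + sect)
  labels
}

#' Per-segment mean myocardial blood flow
#'
#' @param fp_map matrix of voxelwise Fp (MBF) values, NA outside the fit
#'   region, or a parameter-map list from [fit_2cxm_map()].
#' @param labels segment label matrix from [aha_divide()].
#' @param expected_segments optional segment ids to report even when empty
#'   (reported with `NA` mean and zero count).
#' @return data.frame with `segment`, `mean_mbf`, `n_voxels`.
#' @export
per_segment_mbf <- function(fp_map, labels, expected_segments = NULL) {
  if (is.list(fp_map)) fp_map <- fp_map$Fp
  ids <- sort(unique(labels[labels > 0]))
  ids <- sort(unique(c(ids, expected_segments)))
  rows <- lapply(ids, function(s) {
    v <- fp_map[labels == s]
    v <- v[!is.na(v)]
    data.frame(segment = s,
               mean_mbf = if (length(v)) mean(v) else NA_real_,
               n_voxels = length(v))
  })
  do.call(rbind, rows)
}
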