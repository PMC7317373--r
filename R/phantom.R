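## Synthetic short-axis perfusion phantom with analytic ground truth.
##
## The phantom emulates a 3-slice (basal / mid / apical) rest + stress
## first-pass acquisition: an early right-ventricular bolus, a delayed
## left-ventricular (arterial) bolus, and myocardial enhancement generated by
## the 2CXM itself with per-voxel parameters drawn from configured ranges.
## The signal model is linear in concentration, S(t) = S0 (1 + gamma C(t)),
## so quantification is exactly invertible in noiseless mode.

#' Phantom configuration
#'
#' Defaults match the emulated acquisition: 256 x 256 images at 1.2 mm
#' in-plane spacing, three short-axis slices at rest and stress. Frame count
#' and interval are not dictated by the acquisition and default to 50 frames
#' at 1 s. Kinetic ranges give rest MBF ~0.5-1.5 and stress ~1.5-3.5
#' mL/min/mL, in line with reported clinical means (~0.9 rest, ~2.0 stress).
#'
#' @param image_size image side in pixels.
#' @param n_frames number of timeframes (>= 5).
#' @param frame_interval seconds between frames.
#' @param pixel_spacing mm per pixel (isotropic in-plane).
#' @param conditions subset of c("rest", "stress").
#' @param slice_levels subset of c("basal", "mid", "apical").
#' @param slice_scale named radius scale per slice level (apical smallest).
#' @param lv_center_range pixels of uniform jitter of the LV centre about the
#'   image centre (low, high).
#' @param lv_pool_radius_range,myo_thickness_range pixels (basal scale).
#' @param insertion_angle_anterior,insertion_angle_inferior degrees
#'   (counterclockwise as displayed, 0 = image right).
#' @param rv_delay_frames frames by which the RV bolus precedes the LV bolus.
#' @param aif_params per-condition gamma-variate parameters
#'   (t0 s, alpha, beta s, scale = peak concentration).
#' @param kinetic_param_ranges per-condition list of (low, high) ranges for
#'   Fp, vp, PS, ve.
#' @param s0_pool,s0_myo,s0_body,s0_air baseline signal levels (a.u.).
#' @param signal_gain gamma of the linear signal model.
#' @param noise_sd additive Gaussian noise sd as a fraction of the baseline
#'   myocardial signal.
#' @param rician if TRUE, noise is applied as Rician (magnitude of a complex
#'   Gaussian perturbation) instead of additive Gaussian.
#' @param motion_amplitude max |in-plane translation| per frame, pixels
#'   (0 = motion-free mode).
#' @param seed default generator seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256, n_frames = 50,
                           frame_interval = 1.0, pixel_spacing = 1.2,
                           conditions = c("rest", "stress"),
                           slice_levels = c("basal", "mid", "apical"),
                           slice_scale = c(basal = 1.0, mid = 0.85,
                                           apical = 0.7),
                           lv_center_range = c(-10, 10),
                           lv_pool_radius_range = c(16, 20),
                           myo_thickness_range = c(7, 9),
                           insertion_angle_anterior = 120,
                           insertion_angle_inferior = 240,
                           rv_delay_frames = 3,
                           aif_params = list(
                             rest = list(t0 = 10, alpha = 2.5, beta = 3.0,
                                         scale = 5),
                             stress = list(t0 = 8, alpha = 2.0, beta = 2.5,
                                           scale = 5)),
                           kinetic_param_ranges = list(
                             rest = list(Fp = c(0.5, 1.5), vp = c(0.03, 0.08),
                                         PS = c(0.8, 1.5), ve = c(0.15, 0.25)),
                             stress = list(Fp = c(1.5, 3.5), vp = c(0.03, 0.08),
                                           PS = c(0.8, 1.5), ve = c(0.15, 0.25))),
                           s0_pool = 100, s0_myo = 80, s0_body = 40,
                           s0_air = 5, signal_gain = 0.3, noise_sd = 0.05,
                           rician = FALSE, motion_amplitude = 0, seed = 1L) {
  cfg <- as.list(environment())
  if (n_frames < 5) stop("n_frames must be >= 5")
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  stopifnot(rng_ok(lv_center_range), rng_ok(lv_pool_radius_range),
            rng_ok(myo_thickness_range))
  for (cond in conditions) {
    kr <- kinetic_param_ranges[[cond]]
    if (is.null(kr) || !all(vapply(kr, rng_ok, logical(1))))
      stop("invalid kinetic_param_ranges for condition ", cond)
    if (is.null(aif_params[[cond]])) stop("missing aif_params for ", cond)
  }
  max_outer <- max(lv_pool_radius_range) + max(myo_thickness_range)
  if (max_outer * 2.2 + max(abs(lv_center_range)) >= image_size / 2)
    stop("geometry would leave the image bounds; enlarge image_size")
  structure(cfg, class = "phantom_config")
}

#' Gamma-variate bolus curve
#'
#' Standard parametric first-pass bolus model,
#' \deqn{C(t) = s \left(\frac{t - t_0}{\alpha\beta}\right)^{\alpha}
#'       \exp\!\left(\alpha - \frac{t - t_0}{\beta}\right)}
#' for `t > t0` and 0 before arrival. The curve peaks at `t0 + alpha * beta`
#' with peak value `scale`.
#'
#' @param t0 bolus arrival time, seconds.
#' @param alpha shape parameter (> 0).
#' @param beta time constant, seconds (> 0).
#' @param scale peak concentration (> 0).
#' @param times sample times, seconds.
#' @return numeric vector of concentrations (finite, >= 0).
#' @export
gamma_variate_aif <- function(t0, alpha, beta, scale, times) {
  if (alpha <= 0 || beta <= 0 || scale <= 0)
    stop("alpha, beta and scale must be positive")
  stopifnot(all(is.finite(times)))
  dt <- times - t0
  out <- numeric(length(times))
  pos <- dt > 0
  out[pos] <- scale * (dt[pos] / (alpha * beta))^alpha *
    exp(alpha - dt[pos] / beta)
  out
}

## vectorised closed-form 2CXM curves for a matrix of parameter rows
## (Fp, vp, PS, ve all strictly positive), one shared pw-linear AIF
cxm_curves_batch <- function(pars, ca, times) {
  Fp <- pars[, 1] / 60; vp <- pars[, 2]; PS <- pars[, 3] / 60; ve <- pars[, 4]
  stopifnot(all(Fp > 0), all(vp > 0), all(PS > 0), all(ve > 0))
  tr <- -((Fp + PS) / vp + PS / ve)
  dt_ <- PS * Fp / (vp * ve)
  disc <- sqrt(pmax(tr^2 - 4 * dt_, 0))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  m1 <- l1 * ve / PS + 1; m2 <- l2 * ve / PS + 1
  c1 <- (vp * m1 + ve) * Fp / (vp * (m1 - m2))
  c2 <- -(vp * m2 + ve) * Fp / (vp * (m1 - m2))
  n <- length(times)
  y1 <- matrix(0, n, nrow(pars)); y2 <- matrix(0, n, nrow(pars))
  k1 <- -l1; k2 <- -l2
  for (i in 1:(n - 1)) {
    h <- times[i + 1] - times[i]
    m <- (ca[i + 1] - ca[i]) / h
    E1 <- exp(-k1 * h); I1 <- (1 - E1) / k1
    E2 <- exp(-k2 * h); I2 <- (1 - E2) / k2
    y1[i + 1, ] <- E1 * y1[i, ] + ca[i] * I1 + m * (h - I1) / k1
    y2[i + 1, ] <- E2 * y2[i, ] + ca[i] * I2 + m * (h - I2) / k2
  }
  sweep(y1, 2, c1, `*`) + sweep(y2, 2, c2, `*`)
}

## boundary pixels of a binary mask (pixels of the mask 4-adjacent to outside)
.mask_boundary <- function(mask) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- m
  nb <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  m & !nb
}

#' Render phantom anatomy for one slice
#'
#' LV blood pool = disk, myocardium = annulus, RV = crescent abutting the
#' epicardium between the two insertion angles, plus a static body ellipse.
#' Geometry is drawn from the configured ranges using the current RNG state.
#' Insertion points are the epicardial boundary pixels closest to the
#' analytic circle positions at the configured angles.
#'
#' @param config a [phantom_config()].
#' @param slice_level "basal", "mid" or "apical" (sets the radius scale).
#' @return list with binary masks `lv_pool_mask`, `myo_mask`, `rv_mask`,
#'   `body_mask`, `insertion_points` (0-based (row, col)), `centre`, `r_pool`,
#'   `r_epi`.
#' @export
render_geometry <- function(config, slice_level = "basal") {
  n <- config$image_size
  scale <- config$slice_scale[[slice_level]]
  ctr <- (n - 1) / 2 + runif(2, config$lv_center_range[1],
                             config$lv_center_range[2])
  r_pool <- runif(1, config$lv_pool_radius_range[1],
                  config$lv_pool_radius_range[2]) * scale
  thick <- runif(1, config$myo_thickness_range[1],
                 config$myo_thickness_range[2]) * scale
  r_epi <- r_pool + thick
  if (r_epi * 2.2 + max(abs(ctr - (n - 1) / 2)) >= n / 2)
    stop("rendered geometry would leave the image bounds")
  rows <- matrix(0:(n - 1), n, n)
  cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
  d <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  lv_pool <- d <= r_pool
  myo <- d <= r_epi & !lv_pool
  th_a <- config$insertion_angle_anterior
  th_i <- config$insertion_angle_inferior
  ang <- .pixel_angle(rows, cols, ctr)
  delta <- .wrap360(th_i - th_a)
  dir <- if (delta <= 180) 1 else -1
  rel <- .wrap360((ang - th_a) * dir)
  span <- .wrap360((th_i - th_a) * dir)
  rv_w <- r_pool * 0.9
  rv <- d > r_epi & d <= r_epi + rv_w & rel <= span
  body <- ((rows - (n - 1) / 2) / (n * 0.33))^2 +
    ((cols - (n - 1) / 2) / (n * 0.40))^2 <= 1
  ins <- lapply(c(anterior = th_a, inferior = th_i), function(theta) {
    p <- c(ctr[1] - r_epi * sin(theta * pi / 180),
           ctr[2] + r_epi * cos(theta * pi / 180))
    bd <- which(.mask_boundary(myo), arr.ind = TRUE) - 1  # 0-based
    bd[which.min((bd[, 1] - p[1])^2 + (bd[, 2] - p[2])^2), ]
  })
  list(lv_pool_mask = matrix(as.integer(lv_pool), n, n),
       myo_mask = matrix(as.integer(myo), n, n),
       rv_mask = matrix(as.integer(rv), n, n),
       body_mask = matrix(as.integer(body), n, n),
       insertion_points = lapply(ins, as.double),
       centre = ctr, r_pool = r_pool, r_epi = r_epi)
}

#' Generate one subject's phantom series with ground truth
#'
#' Produces one [perfusion_series()] + ground-truth pair per slice level and
#' condition. The slice geometry is drawn once per slice and shared between
#' rest and stress; bolus timing, per-voxel 2CXM parameters, noise and
#' (optional) motion follow the configuration. Output is fully reproducible
#' for a fixed seed.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param subject_id identifier used in the series metadata.
#' @return list of entries, each `list(series, truth)` where `truth` holds
#'   `peak_frame` (0-based), `bbox`, masks, `insertion_points`, `param_maps`,
#'   `aif_true`, `rv_curve` and `motion` (T x 2 shifts).
#' @export
generate_series <- function(config, seed = config$seed,
                            subject_id = sprintf("phantom%04d", seed)) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$n_frames < 5) stop("n_frames must be >= 5")
  set.seed(as.integer(seed) %% 2147483647L)
  times <- (0:(config$n_frames - 1)) * config$frame_interval
  n <- config$image_size
  out <- list()
  for (slice in config$slice_levels) {
    geo <- render_geometry(config, slice)
    for (cond in config$conditions) {
      ap <- config$aif_params[[cond]]
      c_lv <- gamma_variate_aif(ap$t0, ap$alpha, ap$beta, ap$scale, times)
      rv_t0 <- ap$t0 - config$rv_delay_frames * config$frame_interval
      c_rv <- gamma_variate_aif(rv_t0, ap$alpha, ap$beta, ap$scale, times)
      kr <- config$kinetic_param_ranges[[cond]]
      myo_idx <- which(geo$myo_mask != 0)
      nv <- length(myo_idx)
      pars <- cbind(runif(nv, kr$Fp[1], kr$Fp[2]),
                    runif(nv, kr$vp[1], kr$vp[2]),
                    runif(nv, kr$PS[1], kr$PS[2]),
                    runif(nv, kr$ve[1], kr$ve[2]))
      ct <- cxm_curves_batch(pars, c_lv, times)    # T x nv
      s0 <- matrix(config$s0_air, n, n)
      s0[geo$body_mask != 0] <- config$s0_body
      s0[geo$myo_mask != 0] <- config$s0_myo
      s0[geo$lv_pool_mask != 0] <- config$s0_pool
      s0[geo$rv_mask != 0] <- config$s0_pool
      g <- config$signal_gain
      frames <- array(rep(s0, config$n_frames), c(n, n, config$n_frames))
      pool_idx <- which(geo$lv_pool_mask != 0)
      rv_idx <- which(geo$rv_mask != 0)
      plane <- n * n
      for (t in seq_len(config$n_frames)) {
        off <- (t - 1) * plane
        frames[off + pool_idx] <- config$s0_pool * (1 + g * c_lv[t])
        frames[off + rv_idx] <- config$s0_pool * (1 + g * c_rv[t])
        frames[off + myo_idx] <- config$s0_myo * (1 + g * ct[t, ])
      }
      motion <- matrix(0L, config$n_frames, 2)
      if (config$motion_amplitude > 0) {
        motion <- matrix(sample(seq(-config$motion_amplitude,
                                    config$motion_amplitude),
                                2 * config$n_frames, replace = TRUE),
                         config$n_frames, 2)
        for (t in seq_len(config$n_frames))
          frames[, , t] <- shift_image(frames[, , t], motion[t, 1],
                                       motion[t, 2], fill = config$s0_air)
      }
      if (config$noise_sd > 0) {
        sdv <- config$noise_sd * config$s0_myo
        if (config$rician) {
          n1 <- array(rnorm(length(frames), 0, sdv), dim(frames))
          n2 <- array(rnorm(length(frames), 0, sdv), dim(frames))
          frames <- sqrt((frames + n1)^2 + n2^2)
        } else {
          frames <- frames + array(rnorm(length(frames), 0, sdv), dim(frames))
        }
      }
      frames[frames < 0] <- 0
      series <- perfusion_series(frames, rep(config$pixel_spacing, 2), times,
                                 slice_level = slice, condition = cond,
                                 subject_id = subject_id)
      param_maps <- lapply(1:4, function(j) {
        mmap <- matrix(NA_real_, n, n); mmap[myo_idx] <- pars[, j]; mmap
      })
      names(param_maps) <- c("Fp", "vp", "PS", "ve")
      truth <- list(
        peak_frame = which.max(c_lv) - 1L,
        bbox = label_bbox_from_mask(geo$myo_mask, margin = 20),
        myo_mask = geo$myo_mask, lv_pool_mask = geo$lv_pool_mask,
        rv_mask = geo$rv_mask,
        insertion_points = geo$insertion_points,
        param_maps = param_maps,
        aif_true = concentration_curve(times, c_lv),
        rv_curve = concentration_curve(times, c_rv),
        motion = motion)
      out[[paste(slice, cond, sep = "_")]] <- list(series = series,
                                                   truth = truth)
    }
  }
  out
}

#' Generate a cohort of phantom subjects
#'
#' With `lazy = TRUE` the cohort is a list of thunks, each generating its
#' subject on demand (identical output, derived from the same seeds); the
#' training and evaluation code materialises one subject at a time, keeping
#' full-resolution cohorts out of memory.
#'
#' @param config a [phantom_config()].
#' @param n_subjects number of subjects.
#' @param seed base seed; subject i uses a seed derived from `seed + i`.
#' @param lazy return generator closures instead of materialised subjects.
#' @return list of subjects (or closures), each the result of
#'   [generate_series()].
#' @export
generate_cohort <- function(config, n_subjects, seed = config$seed,
                            lazy = FALSE) {
  make <- function(i) generate_series(config, seed = derive_seed(seed, i),
                                      subject_id = sprintf("phantom%04d", i))
  if (lazy) {
    lapply(seq_len(n_subjects), function(i) { force(i); function() make(i) })
  } else {
    lapply(seq_len(n_subjects), make)
  }
}

## materialise a cohort element (subject list or generator closure)
materialize_subject <- function(s) if (is.function(s)) s() else s

## integer translate with constant fill
shift_image <- function(img, dr, dc, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- img[rs - dr, cs - dc]
  out
}

#' Write one phantom subject to disk
#'
#' One NIfTI per slice/condition (float32, spacing in header), masks as uint8
#' NIfTI, ground truth (peak frame, box corners, insertion points) as JSON,
#' parameter maps as NIfTI, AIF as a two-column CSV (time_s, concentration).
#'
#' @param subject result of [generate_series()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(subject)) {
    e <- subject[[key]]
    s <- e$series; tr <- e$truth
    dt <- diff(s$frame_times[1:2])
    write_nifti(s$frames, file.path(dir, paste0(key, ".nii.gz")),
                pixdim = c(s$pixel_spacing, dt), datatype = "float32")
    write_nifti(tr$myo_mask, file.path(dir, paste0(key, "_myo.nii.gz")),
                pixdim = s$pixel_spacing, datatype = "uint8")
    write_nifti(tr$lv_pool_mask, file.path(dir, paste0(key, "_pool.nii.gz")),
                pixdim = s$pixel_spacing, datatype = "uint8")
    pm <- array(unlist(tr$param_maps), c(dim(tr$myo_mask), 4))
    pm[is.na(pm)] <- 0
    write_nifti(pm, file.path(dir, paste0(key, "_params.nii.gz")),
                pixdim = c(s$pixel_spacing, 1), datatype = "float32")
    jsonlite::write_json(
      list(peak_frame = tr$peak_frame,
           bbox = box_corners(tr$bbox, dim(tr$myo_mask)),
           insertion_points = tr$insertion_points),
      file.path(dir, paste0(key, "_truth.json")), auto_unbox = TRUE,
      digits = NA)
    write.csv(data.frame(time_s = tr$aif_true$times,
                         concentration = tr$aif_true$values),
              file.path(dir, paste0(key, "_aif.csv")), row.names = FALSE)
  }
  invisible(dir)
}
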