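## End-to-end orchestration: stage-model training on a phantom cohort, the
## fully automated run (peak frame -> bounding box -> crop -> [optional
## rigid-translation correction] -> segmentation + QC -> insertion points ->
## AIF -> 2CXM -> AHA table), run manifests, and run-vs-run evaluation.

#' Desk-scale architecture profile for the four pipeline stages
#'
#' Channel widths are configuration, not contract; these defaults train in
#' minutes on one CPU against the phantom. The classifier and box networks
#' ingest frames downsampled to `cnn_size`; the U-Nets work on the 96 x 96
#' cropped grid.
#'
#' @param cnn_size CNN input side (downsampled from the acquisition matrix).
#' @param conv_widths,fc_width CNN widths.
#' @param base_filters,levels U-Net width/depth.
#' @param seg_size U-Net input side.
#' @return named list of [arch_spec()]s (`peak`, `bbox`, `seg`, `action`).
#' @export
arch_profile <- function(cnn_size = 64, conv_widths = c(8, 16, 24, 32),
                         fc_width = 64, base_filters = 6, levels = 3,
                         seg_size = 96) {
  list(peak = arch_spec("classifier_cnn", in_channels = 5,
                        in_size = cnn_size, conv_widths = conv_widths,
                        fc_width = fc_width),
       bbox = arch_spec("bbox_cnn", in_channels = 1, in_size = cnn_size,
                        conv_widths = conv_widths, fc_width = fc_width),
       seg = arch_spec("unet_seg", in_size = seg_size,
                       base_filters = base_filters, levels = levels),
       action = arch_spec("unet_action", in_size = seg_size,
                          base_filters = base_filters, levels = levels))
}

.norm01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi > lo) (m - lo) / (hi - lo) else m * 0
}

.delta_target <- function(box, image_dim) {
  prop <- propose_roi(image_dim[1], image_dim[2])
  d <- invert_delta(prop, box)
  c(d$dx / prop$width, d$dy / prop$height, d$sw, d$sh)
}

## crop one frame with the same transform as crop_series (peak frame only,
## avoiding resampling of whole stacks during dataset construction)
.crop_frame <- function(frame, box, side) {
  r <- rasterize_box(box, dim(frame))
  img <- resize_bicubic(frame[(r$row[1] + 1):r$row[2],
                              (r$col[1] + 1):r$col[2]], side, side)
  crop <- list(row0 = r$row[1], col0 = r$col[1], h = r$row[2] - r$row[1],
               w = r$col[2] - r$col[1], out_size = side)
  list(img = img, crop = crop)
}

## one pass over a (possibly lazy) cohort, extracting all stage training
## tensors while holding a single full-resolution subject in memory
.stage_data <- function(cohort, profile, k_neg) {
  side_p <- profile$peak$in_size
  side_b <- profile$bbox$in_size
  side_s <- profile$seg$in_size
  px <- list(); py <- integer()
  bx <- list(); by <- list(); bboxes <- list(); bdims <- list()
  cx <- list(); cm <- list(); pa <- list(); pi_ <- list()
  for (s in cohort) {
    subj <- materialize_subject(s)
    for (e in subj) {
      ns <- normalize_series(e$series)
      nt <- n_frames(ns); pk <- e$truth$peak_frame
      neg <- sample(setdiff(0:(nt - 1), pk), min(k_neg, nt - 1))
      for (t in c(pk, neg)) {
        w <- make_window(ns, t)
        xw <- array(0, c(side_p, side_p, 5))
        for (c_ in 1:5) xw[, , c_] <- resize_bicubic(w[, , c_], side_p, side_p)
        px[[length(px) + 1]] <- xw
        py <- c(py, if (t == pk) 2L else 1L)
      }
      fr <- e$series$frames[, , pk + 1]
      if (e$series$slice_level == "basal") {
        bx[[length(bx) + 1]] <- resize_bicubic(.norm01(fr), side_b, side_b)
        by[[length(by) + 1]] <- .delta_target(e$truth$bbox, dim(fr))
        bboxes[[length(bboxes) + 1]] <- e$truth$bbox
        bdims[[length(bdims) + 1]] <- dim(fr)
      }
      cf <- .crop_frame(fr, e$truth$bbox, side_s)
      cx[[length(cx) + 1]] <- .norm01(cf$img)
      cm[[length(cm) + 1]] <- crop_mask(e$truth$myo_mask, e$truth$bbox, side_s)
      pa[[length(pa) + 1]] <-
        original_to_crop(e$truth$insertion_points$anterior, cf$crop)
      pi_[[length(pi_) + 1]] <-
        original_to_crop(e$truth$insertion_points$inferior, cf$crop)
    }
    rm(subj)
  }
  list(peak = list(x = array(unlist(px), c(side_p, side_p, 5, length(px))),
                   y = py),
       bbox = list(x = array(unlist(bx), c(side_b, side_b, 1, length(bx))),
                   y = matrix(unlist(by), 4), boxes = bboxes, dims = bdims),
       crop = list(x = array(unlist(cx), c(side_s, side_s, 1, length(cx))),
                   masks = array(unlist(cm),
                                 c(side_s, side_s, 1, length(cm))),
                   pts_anterior = do.call(rbind, pa),
                   pts_inferior = do.call(rbind, pi_)))
}

.action_labels <- function(pts, side) {
  n <- nrow(pts)
  y <- array(0L, c(side, side, n))
  for (i in seq_len(n))
    y[, , i] <- build_action_map(c(side, side),
                                 clamp(pts[i, ], 2, side - 3))
  y
}

#' Train all pipeline stage models on a phantom cohort
#'
#' Trains the peak-frame classifier (one positive + `k_neg` random negative
#' windows per series), the bounding-box regressor (basal slices only, per
#' the acquisition geometry), the segmentation U-Net and the two
#' insertion-point action-map U-Nets. Training inputs are cropped with the
#' ground-truth boxes, mirroring training on manually traced labels.
#'
#' @param train_cohort,val_cohort cohorts from [generate_cohort()].
#' @param cfg a [train_config()] for the two image-level CNNs; the desk
#'   preset is the intended scale.
#' @param cfg_unet a [train_config()] for the three U-Nets; by default
#'   derived from `cfg` with a smaller batch (U-Net iterations cost more on
#'   CPU).
#' @param profile an [arch_profile()].
#' @param k_neg negative windows per series for the peak classifier.
#' @param verbose print per-stage progress.
#' @return list of trained models: `peak`, `bbox`, `seg`, `anterior`,
#'   `inferior`.
#' @export
train_pipeline_models <- function(train_cohort, val_cohort,
                                  cfg = train_config(preset = "desk"),
                                  cfg_unet = NULL,
                                  profile = arch_profile(), k_neg = 4,
                                  verbose = TRUE) {
  if (is.null(cfg_unet))
    cfg_unet <- modifyList(cfg, list(batch_size = 8,
                                     max_iter = min(cfg$max_iter, 220),
                                     patience = min(cfg$patience, 120)))
  ## the box regressor is the cheapest network per iteration and benefits
  ## from a longer schedule: give it at least 800 iterations
  cfg_bbox <- modifyList(cfg, list(max_iter = max(cfg$max_iter, 800),
                                   patience = max(cfg$patience, 300)))
  say <- function(...) if (verbose) message(sprintf(...))
  rg <- cfg$augment
  set.seed(derive_seed(cfg$seed, 11))
  say("building stage training data (one pass per subject)")
  data_tr <- .stage_data(train_cohort, profile, k_neg)
  data_va <- .stage_data(val_cohort, profile, k_neg)
  peak_tr <- data_tr$peak; peak_va <- data_va$peak
  peak_sampler <- function(idx) {
    x <- peak_tr$x[, , , idx, drop = FALSE]
    if (!is.null(rg)) {
      for (j in seq_along(idx))
        x[, , , j] <- augment(x[, , , j], ranges = rg)$image
    }
    list(x = x, y = peak_tr$y[idx])
  }
  say("peak classifier: training")
  m_peak <- train_model(profile$peak, peak_tr, peak_va, cfg,
                        sampler = peak_sampler)

  say("bounding box: training (basal slices)")
  bb_tr <- data_tr$bbox; bb_va <- data_va$bbox
  bb_sampler <- function(idx) {
    x <- bb_tr$x[, , , idx, drop = FALSE]
    y <- bb_tr$y[, idx, drop = FALSE]
    if (!is.null(rg)) {
      side_b <- profile$bbox$in_size
      for (j in seq_along(idx)) {
        dims <- bb_tr$dims[[idx[j]]]
        px <- dims[1] / side_b         # full-res pixels per network pixel
        tr_net <- runif(2, -rg$translate, rg$translate)
        sc <- 1 + runif(1, -rg$scale, rg$scale)
        ctr_n <- (side_b - 1) / 2
        Ai <- diag(2) / sc
        M <- cbind(Ai, c(ctr_n, ctr_n) - Ai %*% (c(ctr_n, ctr_n) + tr_net))
        img <- warp_affine(x[, , 1, j], M, "bilinear")
        gain <- 1 + runif(1, -rg$intensity, rg$intensity)
        img <- clamp(img * gain + rnorm(length(img), 0,
                                        runif(1, 0, rg$noise)), 0, 1)
        x[, , 1, j] <- img
        box <- bb_tr$boxes[[idx[j]]]
        ctr_f <- (dims - 1) / 2
        box2 <- bounding_box((box$center - ctr_f) * sc + ctr_f + tr_net * px,
                             box$height * sc, box$width * sc)
        y[, j] <- .delta_target(box2, dims)
      }
    }
    list(x = x, y = y)
  }
  m_bbox <- train_model(profile$bbox, bb_tr, bb_va, cfg_bbox,
                        sampler = bb_sampler)

  seg_side <- profile$seg$in_size
  cs_tr <- data_tr$crop; cs_va <- data_va$crop
  seg_sampler <- function(idx) {
    x <- cs_tr$x[, , , idx, drop = FALSE]
    y <- cs_tr$masks[, , , idx, drop = FALSE]
    if (!is.null(rg)) {
      for (j in seq_along(idx)) {
        a <- augment(x[, , 1, j], y[, , 1, j], rg, label_type = "mask")
        x[, , 1, j] <- a$image; y[, , 1, j] <- a$label
      }
    }
    list(x = x, y = y)
  }
  say("segmentation: training")
  m_seg <- train_model(profile$seg, list(x = cs_tr$x, y = cs_tr$masks),
                       list(x = cs_va$x, y = cs_va$masks), cfg_unet,
                       sampler = seg_sampler)

  action_model <- function(pts_tr, pts_va, which) {
    say("action map (%s): training", which)
    y_va <- .action_labels(pts_va, seg_side)
    smp <- function(idx) {
      x <- cs_tr$x[, , , idx, drop = FALSE]
      pts <- pts_tr[idx, , drop = FALSE]
      if (!is.null(rg)) {
        for (j in seq_along(idx)) {
          a <- augment(x[, , 1, j], pts[j, ], rg, label_type = "points")
          x[, , 1, j] <- a$image; pts[j, ] <- a$label
        }
      }
      list(x = x, y = .action_labels(pts, seg_side))
    }
    train_model(profile$action,
                list(x = cs_tr$x, y = .action_labels(pts_tr, seg_side)),
                list(x = cs_va$x, y = y_va), cfg_unet, sampler = smp)
  }
  m_ant <- action_model(cs_tr$pts_anterior, cs_va$pts_anterior, "anterior")
  m_inf <- action_model(cs_tr$pts_inferior, cs_va$pts_inferior, "inferior")
  list(peak = m_peak, bbox = m_bbox, seg = m_seg, anterior = m_ant,
       inferior = m_inf)
}

#' Rigid-translation motion correction toward a reference frame
#'
#' Simple integer-shift registration by exhaustive intensity
#' cross-correlation within `max_shift` pixels, aligning every frame to the
#' peak frame. A fallback utility (off by default in [run_pipeline()]); the
#' phantom's default mode is motion-free.
#'
#' @param series a (cropped) [perfusion_series()].
#' @param ref 0-based reference frame index.
#' @param max_shift search radius in pixels.
#' @return the series with shifted frames and an attached `shifts` attribute.
#' @export
motion_correct_series <- function(series, ref, max_shift = 5) {
  reff <- series$frames[, , ref + 1]
  nt <- n_frames(series)
  shifts <- matrix(0L, nt, 2)
  for (t in seq_len(nt)) {
    fr <- series$frames[, , t]
    best <- c(0L, 0L); bv <- -Inf
    for (dr in -max_shift:max_shift) {
      for (dc in -max_shift:max_shift) {
        sh <- shift_image(fr, dr, dc)
        v <- sum(sh * reff)
        if (v > bv) { bv <- v; best <- c(dr, dc) }
      }
    }
    shifts[t, ] <- best
    series$frames[, , t] <- shift_image(fr, best[1], best[2])
  }
  attr(series, "shifts") <- shifts
  series
}

#' Run the full automated pipeline on one subject
#'
#' Executes peak detection, bounding-box detection on the basal slice
#' (reused for mid and apical), cropping, optional rigid-translation
#' correction, segmentation with closed-loop QC and fallback, insertion-point
#' detection, AIF extraction, 2CXM fitting and AHA segment reporting. Any
#' stage's hard error is recorded in the manifest (`status = "failed"`,
#' `failed_stage`) and downstream stages for that series are skipped; the run
#' itself is fully non-interactive.
#'
#' @param subject list of entries from [generate_series()] (or assembled from
#'   [read_series()] with optional `truth`).
#' @param models model bundle from [train_pipeline_models()]; may be NULL
#'   when every network stage is replaced by ground truth via `use_truth`.
#' @param fit_mode "segment" fits the 2CXM to each AHA segment's mean curve;
#'   "voxel" fits voxelwise ([fit_2cxm_map()]) and averages Fp per segment.
#' @param use_truth subset of c("peak", "bbox", "seg", "landmarks"): stages
#'   to take from ground truth instead of the networks (isolates
#'   quantification from detection).
#' @param motion_correct apply [motion_correct_series()] after cropping.
#' @param baseline_frames,gamma signal-to-concentration settings.
#' @param crop_size analysis grid side.
#' @param keep_intermediates also store the segmentation mask per series in
#'   the manifest (in-memory use; not meant for JSON serialisation).
#' @param prior a [cxm_prior()] regularising the kinetic fits (NULL for plain
#'   least squares).
#' @return manifest list: per-series stage outputs, QC flags and the
#'   per-segment MBF table (`mbf` data.frame with condition, slice, segment,
#'   mean_mbf, n_voxels).
#' @export
run_pipeline <- function(subject, models = NULL,
                         fit_mode = c("segment", "voxel"),
                         use_truth = character(), motion_correct = FALSE,
                         baseline_frames = 5, gamma = 1.0, crop_size = 96,
                         keep_intermediates = FALSE, prior = cxm_prior()) {
  fit_mode <- match.arg(fit_mode)
  manifest <- list(subject_id = subject[[1]]$series$subject_id,
                   fit_mode = fit_mode, use_truth = as.list(use_truth),
                   series = list(), status = "ok")
  conditions <- unique(vapply(subject, function(e) e$series$condition, ""))
  mbf_rows <- list()
  for (cond in conditions) {
    keys <- names(subject)[vapply(subject, function(e)
      e$series$condition == cond, TRUE)]
    basal_key <- keys[vapply(subject[keys], function(e)
      e$series$slice_level == "basal", TRUE)][1]
    ## stage 1-2 on the basal slice: peak frame, then the shared box
    box <- NULL
    basal <- subject[[basal_key]]
    rec_basal <- list()
    box <- tryCatch({
      peak_b <- if ("peak" %in% use_truth) basal$truth$peak_frame else
        detect_peak_frame(basal$series, models$peak)$frame
      rec_basal$basal_peak <- peak_b
      if ("bbox" %in% use_truth) basal$truth$bbox else
        detect_bbox(basal$series$frames[, , peak_b + 1], models$bbox)
    }, error = function(e) {
      manifest$status <<- "failed"
      rec_basal$error <<- conditionMessage(e)
      NULL
    })
    for (key in keys) {
      e <- subject[[key]]
      rec <- c(list(key = key, condition = cond,
                    slice = e$series$slice_level), rec_basal)
      res <- tryCatch({
        if (is.null(box)) stop("bounding-box stage failed for this condition")
        rec$stage <- "peak"
        peak <- if ("peak" %in% use_truth) e$truth$peak_frame else
          detect_peak_frame(e$series, models$peak)$frame
        rec$peak_frame <- peak
        rec$stage <- "crop"
        rec$box <- box_corners(box, dim(e$series$frames)[1:2])
        cs <- crop_series(e$series, box, out_size = crop_size)
        crop <- attr(cs, "crop")
        if (motion_correct) cs <- motion_correct_series(cs, peak)
        rec$stage <- "segment"
        if ("seg" %in% use_truth) {
          mask <- crop_mask(e$truth$myo_mask, box, crop_size)
          seg <- list(mask = mask, used_frame = peak,
                      passed_qc = qc_closed_loop(mask))
        } else {
          seg <- segment_with_fallback(cs, peak, models$seg)
        }
        rec$seg_qc <- seg$passed_qc
        rec$seg_used_frame <- seg$used_frame
        if (!seg$passed_qc) stop("segmentation failed closed-loop QC")
        rec$stage <- "landmarks"
        if ("landmarks" %in% use_truth) {
          pts <- list(
            anterior = original_to_crop(e$truth$insertion_points$anterior,
                                        crop),
            inferior = original_to_crop(e$truth$insertion_points$inferior,
                                        crop))
          rec$landmark_flags <- c("truth", "truth")
        } else {
          det <- detect_insertion_points(
            cs$frames[, , seg$used_frame + 1], models$anterior,
            models$inferior, crop = crop)
          pts <- list(anterior = det$anterior$point,
                      inferior = det$inferior$point)
          rec$landmark_flags <- c(det$anterior$flag, det$inferior$flag)
        }
        rec$insertion_points <- pts
        rec$insertion_points_original <- lapply(pts, crop_to_original, crop)
        if (keep_intermediates) rec$seg_mask <- seg$mask
        rec$stage <- "aif"
        interior <- interior_from_mask(seg$mask)
        aif_res <- extract_aif(cs, interior, peak,
                               baseline_frames = baseline_frames,
                               gamma = gamma)
        rec$aif_region_voxels <- sum(aif_res$region)
        rec$aif_flag <- aif_res$flag
        rec$stage <- "quantify"
        labels <- aha_divide(seg$mask, pts, e$series$slice_level)
        seg_tab <- quantify_segments(cs, seg$mask, labels, aif_res$aif,
                                     fit_mode = fit_mode,
                                     baseline_frames = baseline_frames,
                                     gamma = gamma, prior = prior)
        rec$mbf <- seg_tab
        rec$stage <- "done"
        rec
      }, error = function(err) {
        rec$error <- conditionMessage(err)
        rec$failed_stage <- rec$stage %||% "setup"
        manifest$status <<- "failed"
        rec
      })
      manifest$series[[key]] <- res
      if (!is.null(res$mbf)) {
        tab <- res$mbf
        tab$condition <- cond
        tab$slice <- e$series$slice_level
        mbf_rows[[length(mbf_rows) + 1]] <- tab
      }
    }
  }
  manifest$mbf <- if (length(mbf_rows)) do.call(rbind, mbf_rows) else NULL
  manifest
}

#' Quantify per-segment MBF from a cropped series
#'
#' Converts signal to concentration and fits the 2CXM either to each
#' segment's mean concentration curve (`fit_mode = "segment"`) or voxelwise
#' with segment averaging of Fp (`fit_mode = "voxel"`).
#'
#' @param cropped_series cropped [perfusion_series()].
#' @param mask binary myocardial mask on the cropped grid.
#' @param labels AHA segment labels from [aha_divide()].
#' @param aif a [concentration_curve()].
#' @param fit_mode "segment" or "voxel".
#' @param baseline_frames,gamma signal-model settings.
#' @param prior a [cxm_prior()] or NULL, passed to the fitters.
#' @param erode_px rounds of mask erosion before curve extraction, guarding
#'   against blood-pool partial-volume contamination at the resampled mask
#'   boundary; automatically reduced when a segment would lose all voxels
#'   (thin apical rings).
#' @return data.frame with `segment`, `mean_mbf`, `n_voxels`.
#' @export
quantify_segments <- function(cropped_series, mask, labels, aif,
                              fit_mode = c("segment", "voxel"),
                              baseline_frames = 5, gamma = 1.0,
                              erode_px = 2, prior = cxm_prior()) {
  fit_mode <- match.arg(fit_mode)
  times <- cropped_series$frame_times
  ids_full <- sort(unique(labels[labels > 0]))
  while (erode_px > 0) {
    er <- erode_mask(mask, erode_px)
    if (all(vapply(ids_full, function(s) any(labels == s & er != 0),
                   logical(1)))) break
    erode_px <- erode_px - 1
  }
  mask <- if (erode_px > 0) erode_mask(mask, erode_px) else
    matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (fit_mode == "voxel") {
    d <- dim(cropped_series$frames)
    conc <- array(0, d)
    fmat <- matrix(cropped_series$frames, d[1] * d[2], d[3])
    s0 <- rowMeans(fmat[, seq_len(baseline_frames), drop = FALSE])
    s0[s0 <= 0] <- NA
    conc <- array((fmat - s0) / (gamma * s0), d)
    maps <- fit_2cxm_map(conc, aif, mask, prior = prior)
    return(per_segment_mbf(maps, labels))
  }
  rows <- lapply(ids_full, function(s) {
    vox <- labels == s & mask != 0
    if (!any(vox))
      return(data.frame(segment = s, mean_mbf = NA_real_, n_voxels = 0L))
    sig <- apply(cropped_series$frames, 3, function(fr) mean(fr[vox]))
    ct <- signal_to_conc(sig, times, baseline_frames, gamma)
    fit <- fit_2cxm(ct, aif, prior = prior)
    data.frame(segment = s, mean_mbf = fit$params$Fp, n_voxels = sum(vox))
  })
  do.call(rbind, rows)
}

#' Write a run manifest as JSON
#'
#' Deterministic content (no timestamps): identical inputs give
#' byte-identical manifests.
#'
#' @param manifest from [run_pipeline()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Extract the 16-segment MBF table from a manifest
#'
#' @param manifest from [run_pipeline()].
#' @return data.frame with `condition`, `slice`, `segment`, `mean_mbf`,
#'   `n_voxels`.
#' @export
mbf_table <- function(manifest) manifest$mbf

#' Agreement statistics between two runs' MBF tables
#'
#' Joins two per-segment MBF tables on (condition, segment) and computes
#' Bland-Altman bias and limits of agreement, ICC(2,1) and the
#' through-origin regression slope, mirroring a per-segment method-agreement
#' analysis between an automated and a reference processing arm.
#'
#' @param tab_a,tab_b data.frames as returned by [mbf_table()].
#' @return list with `bland_altman`, `icc`, `slope`, `n_pairs`, and
#'   `bias_percent` (bias as a percentage of the mean MBF).
#' @export
evaluate_agreement <- function(tab_a, tab_b) {
  key <- function(t) paste(t$condition, t$segment, sep = ":")
  m <- merge(data.frame(k = key(tab_a), a = tab_a$mean_mbf),
             data.frame(k = key(tab_b), b = tab_b$mean_mbf), by = "k")
  m <- m[is.finite(m$a) & is.finite(m$b), ]
  ba <- bland_altman(m$a, m$b)
  list(bland_altman = ba,
       icc = icc_agreement(m$a, m$b),
       slope = slope_through_origin(m$b, m$a),
       n_pairs = nrow(m),
       bias_percent = 100 * ba$bias / mean(c(m$a, m$b)))
}
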