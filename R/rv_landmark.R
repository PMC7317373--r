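## Stage 4: RV insertion-point detection via supervised action maps.
## Each pixel is labelled with the direction (left/right/up/down) toward the
## landmark; the four class regions are separated by the two diagonals of
## slope +/-1 through the landmark, so fitting fixed-slope lines to the
## partition boundaries and intersecting them recovers the landmark.

.ACTION_CLASSES <- c("left", "right", "up", "down")

#' Build the action map for a landmark
#'
#' For pixel p with `dr = landmark_row - p_row`, `dc = landmark_col - p_col`:
#' `right`/`left` when |dc| > |dr| (by the sign of dc), `down`/`up` when
#' |dr| > |dc| (by the sign of dr); ties |dr| == |dc| take the horizontal
#' class (`right` when dc >= 0 else `left`), including the landmark pixel
#' itself (`right`).
#'
#' @param shape (H, W).
#' @param landmark 0-based (row, col), inside the image.
#' @return integer matrix with classes coded 1 = left, 2 = right, 3 = up,
#'   4 = down.
#' @export
build_action_map <- function(shape, landmark) {
  H <- shape[1]; W <- shape[2]
  if (landmark[1] < 0 || landmark[1] > H - 1 ||
      landmark[2] < 0 || landmark[2] > W - 1)
    stop("landmark outside the image")
  dr <- landmark[1] - matrix(0:(H - 1), H, W)
  dc <- landmark[2] - matrix(0:(W - 1), H, W, byrow = TRUE)
  map <- matrix(0L, H, W)
  horiz <- abs(dc) >= abs(dr)
  map[horiz & dc >= 0] <- 2L
  map[horiz & dc < 0] <- 1L
  map[!horiz & dr > 0] <- 4L
  map[!horiz & dr < 0] <- 3L
  map
}

## boundary pixels between two class sets: pixels of either set 4-adjacent to
## the other; returns 0-based (row, col) pairs
.boundary_pixels <- function(map, class_a, class_b) {
  H <- nrow(map); W <- ncol(map)
  a <- map == class_a; b <- map == class_b
  hit <- matrix(FALSE, H, W)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (s in shifts) {
    bs <- matrix(FALSE, H, W)
    r_src <- max(1, 1 - s[1]):min(H, H - s[1])
    c_src <- max(1, 1 - s[2]):min(W, W - s[2])
    bs[r_src + s[1], c_src + s[2]] <- b[r_src, c_src]
    hit <- hit | (a & bs)
    as <- matrix(FALSE, H, W)
    as[r_src + s[1], c_src + s[2]] <- a[r_src, c_src]
    hit <- hit | (b & as)
  }
  which(hit, arr.ind = TRUE) - 1
}

#' Infer the landmark from an action map
#'
#' Boundary pixels between the `up`/`right` and `down`/`left` class pairs lie
#' on the slope -1 diagonal (`row + col = const`), those between `up`/`left`
#' and `down`/`right` on the slope +1 diagonal (`row - col = const`). A line
#' with fixed slope is fit to each set by least squares (the intercept is the
#' mean of `row + col`, respectively `row - col`) and the landmark is the
#' intersection. Against label noise in predicted maps, the fit is robustified
#' by centring on the median intercept and refitting on the boundary pixels
#' within `trim` of it (exact maps are unaffected). With fewer than
#' `min_pixels` boundary pixels per line, or a missing class, the flagged
#' class-centroid heuristic is used instead.
#'
#' @param map integer action-map matrix (codes as [build_action_map()]).
#' @param min_pixels minimum boundary pixels required per line.
#' @param trim half-width (pixels) of the inlier band around the median
#'   intercept.
#' @return list with `point` (continuous 0-based (row, col)) and `flag`
#'   ("ok" or "centroid_fallback").
#' @export
infer_point <- function(map, min_pixels = 3, trim = 3) {
  ## the true partition boundary concentrates on a single diagonal while
  ## label noise scatters spurious boundary pixels uniformly: centre on the
  ## modal intercept, then average the inlier band
  robust_intercept <- function(v) {
    tab <- table(round(v))
    centre <- as.numeric(names(tab)[which.max(tab)])
    keep <- v[abs(v - centre) <= trim]
    if (length(keep) < min_pixels) NULL else mean(keep)
  }
  present <- vapply(1:4, function(k) any(map == k), logical(1))
  if (all(present)) {
    bd_neg <- rbind(.boundary_pixels(map, 3, 2), .boundary_pixels(map, 4, 1))
    bd_pos <- rbind(.boundary_pixels(map, 3, 1), .boundary_pixels(map, 4, 2))
    if (nrow(bd_neg) >= min_pixels && nrow(bd_pos) >= min_pixels) {
      a <- robust_intercept(bd_neg[, 1] + bd_neg[, 2])  # row + col (slope -1)
      b <- robust_intercept(bd_pos[, 1] - bd_pos[, 2])  # row - col (slope +1)
      if (!is.null(a) && !is.null(b))
        return(list(point = c((a + b) / 2, (a - b) / 2), flag = "ok"))
    }
  }
  ## fallback: horizontal classes locate the row, vertical classes the column
  lr <- which(map == 1L | map == 2L, arr.ind = TRUE)
  ud <- which(map == 3L | map == 4L, arr.ind = TRUE)
  if (nrow(lr) == 0 || nrow(ud) == 0) stop("degenerate action map")
  list(point = c(mean(lr[, 1]) - 1, mean(ud[, 2]) - 1),
       flag = "centroid_fallback")
}

#' Detect both RV insertion points on a cropped peak frame
#'
#' One action-map network per landmark (anterior and inferior). Each network
#' predicts a per-pixel 4-class map (argmax of the softmax output) from
#' which [infer_point()] recovers the landmark; coordinates are returned in
#' the cropped grid and, when the series carries a `crop` attribute, also in
#' original-image coordinates.
#'
#' @param image cropped peak frame matrix (normalized to [0, 1] internally).
#' @param model_anterior,model_inferior trained `unet_action` models.
#' @param crop optional crop transform (the `crop` attribute of
#'   [crop_series()]'s result).
#' @return list with `anterior` and `inferior`, each holding `point`
#'   (cropped), `point_original` (or NULL), `flag`, and `map`.
#' @export
detect_insertion_points <- function(image, model_anterior, model_inferior,
                                    crop = NULL) {
  lo <- min(image); hi <- max(image)
  img <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  one <- function(model) {
    stopifnot(model$arch$kind == "unet_action")
    side <- model$arch$in_size
    x <- array(if (all(dim(img) == side)) img else
      resize_bicubic(img, side, side), c(side, side, 1, 1))
    z <- nn_forward(model, x)$out[, , , 1]
    map <- apply(z, c(1, 2), which.max)
    est <- infer_point(map)
    list(point = est$point,
         point_original = if (!is.null(crop))
           crop_to_original(est$point, crop) else NULL,
         flag = est$flag, map = map)
  }
  list(anterior = one(model_anterior), inferior = one(model_inferior))
}

#' Euclidean landmark error in millimetres
#'
#' Distance with anisotropic pixel spacing:
#' `sqrt((drow * s_row)^2 + (dcol * s_col)^2)`.
#'
#' @param p,q 0-based (row, col) points in the same coordinate frame.
#' @param spacing mm per pixel, length 1 or 2 (row, col).
#' @return distance in mm.
#' @export
landmark_error_mm <- function(p, q, spacing = c(1.2, 1.2)) {
  spacing <- rep(spacing, length.out = 2)
  sqrt(((p[1] - q[1]) * spacing[1])^2 + ((p[2] - q[2]) * spacing[2])^2)
}
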