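#' Segment a doublet image into a binary mask
#'
#' Global Otsu thresholding, hole filling and retention of the largest
#' connected component — the automated counterpart of drawing around the
#' doublet by hand in an image viewer. Works on a plain numeric matrix
#' (any intensity range).
#'
#' @param image Numeric matrix (one frame).
#' @param pixel_size Micrometres per pixel.
#' @param foreground `"bright"` (default, synthetic silhouettes) or `"dark"`
#'   (typical stereomicroscope images of dark spheroids on a light field).
#' @param min_area Minimum foreground area in pixels below which the frame is
#'   rejected with error `"no object found"`.
#' @return A list of class `segmentation_mask`: `mask` (logical matrix),
#'   `labels` (integer matrix of retained components), `n_components`
#'   (1 for a touching doublet, 2 when the spheroids are still separate),
#'   `pixel_size`.
#' @export
segment_doublet <- function(image, pixel_size = 1,
                            foreground = c("bright", "dark"),
                            min_area = 100) {
  foreground <- match.arg(foreground)
  check_positive(pixel_size, "pixel_size")
  rng <- range(image)
  img01 <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  if (foreground == "dark") img01 <- 1 - img01
  thr <- if (diff(rng) > 0) EBImage::otsu(EBImage::Image(img01)) else 1
  bw <- img01 > thr
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0 || max(sizes) < min_area) abort("no object found")
  # keep the largest component, plus a second one if it is comparably sized
  # (a not-yet-touching pair)
  ord <- order(sizes, decreasing = TRUE)
  keep <- ord[1]
  if (length(sizes) > 1 && sizes[ord[2]] >= max(min_area, 0.2 * sizes[ord[1]])) {
    keep <- ord[1:2]
  }
  labels <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_along(keep)) labels[lab == keep[k]] <- k
  structure(
    list(mask = labels > 0L, labels = labels, n_components = length(keep),
         pixel_size = pixel_size),
    class = "segmentation_mask"
  )
}

# area-per-unit-length width profile of a pixel set along a unit axis
width_profile <- function(s) {
  bins <- floor(s - min(s))
  w <- tabulate(bins + 1L)
  list(w = w, s0 = min(s))
}

smooth_running <- function(x, k = 5) {
  n <- length(x)
  if (n < k) return(x)
  half <- (k - 1) %/% 2
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

kasa_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  co <- qr.solve(A, x^2 + y^2)
  c(cx = co[[1]], cy = co[[2]], r = sqrt(co[[3]] + co[[1]]^2 + co[[2]]^2))
}

boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)] & mask
  which(mask & !interior, arr.ind = TRUE)
}

#' Measure doublet geometry from a segmentation mask
#'
#' Finds the doublet axis as the principal axis of the foreground and the
#' neck plane as the interior minimum of the width profile between the two
#' lobe maxima. Each lobe's outer boundary (an exact circular arc away from
#' the neck) is then fitted with a circle; the lobe radii are the fitted
#' radii (plus the half-pixel centre-to-edge offset of boundary pixels) and
#' the neck radius is the half-chord of the fitted circle pair, which on
#' ideal two-sphere geometry coincides with half the minimal width. Fully
#' fused (unimodal-profile) masks raise `"neck undefined"`.
#'
#' @param mask A `segmentation_mask` from [segment_doublet()].
#' @return A one-row tibble (`frame_geometry`): `neck_radius_um`,
#'   `radius_a_um`, `radius_b_um`, `axis_angle_rad`, `centroid_*`, `status`
#'   (`"ok"`, `"separated"`, or an error is thrown for `"neck undefined"`).
#' @export
measure_pair_geometry <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  px <- mask$pixel_size
  if (mask$n_components == 2) {
    geo <- purrr::map(1:2, function(k) {
      idx <- which(mask$labels == k, arr.ind = TRUE)
      list(r = sqrt(nrow(idx) / pi) * px,
           cx = mean(idx[, 2] - 0.5) * px, cy = mean(idx[, 1] - 0.5) * px)
    })
    geo <- geo[order(purrr::map_dbl(geo, "cx"))]
    ang <- atan2(geo[[2]]$cy - geo[[1]]$cy, geo[[2]]$cx - geo[[1]]$cx)
    return(tibble::tibble(
      neck_radius_um = 0, radius_a_um = geo[[1]]$r, radius_b_um = geo[[2]]$r,
      axis_angle_rad = ang,
      centroid_a_x_um = geo[[1]]$cx, centroid_a_y_um = geo[[1]]$cy,
      centroid_b_x_um = geo[[2]]$cx, centroid_b_y_um = geo[[2]]$cy,
      status = "separated"
    ))
  }
  idx <- which(mask$mask, arr.ind = TRUE)
  xy <- cbind(idx[, 2] - 0.5, idx[, 1] - 0.5)   # x = col, y = row, px units
  ctr <- colMeans(xy)
  xyc <- sweep(xy, 2, ctr)
  ev <- eigen(crossprod(xyc) / nrow(xyc), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  ang <- atan2(axis[2], axis[1])
  s <- xyc %*% axis
  prof <- width_profile(s)
  w <- prof$w
  ws <- smooth_running(w, 5)
  n <- length(w)
  if (n < 5) abort("neck undefined")
  # neck plane = deepest interior valley: the bin whose smoothed width sits
  # furthest below the enclosing maxima on both sides (immune to the ~1-px
  # aliasing ripple of the binned profile)
  L <- cummax(ws)
  R <- rev(cummax(rev(ws)))
  score <- pmin(L, R) - ws
  interior <- 3:(n - 2)
  v <- interior[which.max(score[interior])]
  if (score[v] < max(3, 0.05 * max(ws))) abort("neck undefined")
  s_v <- prof$s0 + v - 0.5                  # neck plane, axial coordinate
  # circle fit per lobe on boundary pixels clear of the neck kink
  bd <- boundary_pixels(mask$mask)
  bxy <- cbind(bd[, 2] - 0.5, bd[, 1] - 0.5)
  bs <- sweep(bxy, 2, ctr) %*% axis
  margin <- 5
  fit_lobe <- function(sel) {
    if (sum(sel) < 8) return(NULL)
    cf <- kasa_circle(bxy[sel, 1], bxy[sel, 2])
    if (!all(is.finite(cf))) return(NULL)
    cf
  }
  fa <- fit_lobe(bs < s_v - margin)
  fb <- fit_lobe(bs > s_v + margin)
  if (is.null(fa) || is.null(fb)) abort("neck undefined")
  # boundary pixel centres sit ~half a pixel inside the true edge
  ra <- (fa[["r"]] + 0.5) * px
  rb <- (fb[["r"]] + 0.5) * px
  d <- sqrt((fa[["cx"]] - fb[["cx"]])^2 + (fa[["cy"]] - fb[["cy"]])^2) * px
  xa <- (d^2 + ra^2 - rb^2) / (2 * d)
  neck <- sqrt(max(ra^2 - xa^2, 0))
  tibble::tibble(
    neck_radius_um = neck, radius_a_um = ra, radius_b_um = rb,
    axis_angle_rad = ang,
    centroid_a_x_um = fa[["cx"]] * px, centroid_a_y_um = fa[["cy"]] * px,
    centroid_b_x_um = fb[["cx"]] * px, centroid_b_y_um = fb[["cy"]] * px,
    status = "ok"
  )
}

#' Track a doublet through an image stack into a neck series
#'
#' Segments and measures every frame, assembling a [neck_series()]. The
#' initial average radius R0 is frozen from the first frame (mean of the two
#' lobe radii, whether touching or still separate). Frames where segmentation
#' or geometry fails — including fully fused frames with an undefined neck —
#' are flagged missing rather than aborting the series.
#'
#' @param stack 3-D array rows x cols x frames (e.g. from
#'   [render_fusion_frames()] or [read_frames_tiff()]).
#' @param times Frame times in hours, one per frame.
#' @param pixel_size Micrometres per pixel (defaults to the stack attribute).
#' @param ... Passed to [segment_doublet()].
#' @return A [neck_series()].
#' @export
track_series <- function(stack, times = attr(stack, "time_h"),
                         pixel_size = attr(stack, "pixel_size"), ...) {
  if (is.null(pixel_size)) abort("`pixel_size` is required")
  if (is.null(times) || length(times) != dim(stack)[3]) {
    abort("`times` must have one entry per frame")
  }
  rows <- purrr::map(seq_len(dim(stack)[3]), function(i) {
    tryCatch(
      measure_pair_geometry(segment_doublet(stack[, , i], pixel_size, ...)),
      error = function(e) tibble::tibble(
        neck_radius_um = NA_real_, radius_a_um = NA_real_,
        radius_b_um = NA_real_, axis_angle_rad = NA_real_,
        centroid_a_x_um = NA_real_, centroid_a_y_um = NA_real_,
        centroid_b_x_um = NA_real_, centroid_b_y_um = NA_real_,
        status = conditionMessage(e)
      )
    )
  })
  geo <- dplyr::bind_rows(rows)
  first_ok <- which(!is.na(geo$radius_a_um))[1]
  if (is.na(first_ok)) abort("no frame yielded a valid geometry")
  R0 <- mean(c(geo$radius_a_um[first_ok], geo$radius_b_um[first_ok]))
  out <- neck_series(
    time_h = times, neck_radius_um = geo$neck_radius_um,
    radius_a_um = geo$radius_a_um, radius_b_um = geo$radius_b_um,
    R0_um = R0
  )
  attr(out, "frame_geometry") <- geo
  out
}
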