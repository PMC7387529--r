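#' Centre distance of two intersecting circles with a given neck half-chord
#'
#' Inverts the circle-circle intersection chord relation: for lobe radii
#' `Ra`, `Rb` and neck half-chord `r0`, finds the centre distance `d` such
#' that the intersection lens has half-chord `r0`. For equal radii this is
#' the closed form \eqn{d = 2\sqrt{R^2 - r_0^2}}; for unequal radii the
#' monotone relation is solved numerically.
#'
#' @param r0 Neck half-chord (same units as radii), `0 <= r0 <= min(Ra, Rb)`.
#' @param Ra,Rb Lobe radii.
#' @return Centre distance `d`; `Ra + Rb` when `r0 = 0` (tangent disks) and
#'   `0` when `r0 = Ra = Rb` (full coalescence).
#' @export
doublet_center_distance <- function(r0, Ra, Rb) {
  check_positive(Ra, "Ra"); check_positive(Rb, "Rb")
  check_nonneg(r0, "r0")
  if (r0 > min(Ra, Rb) + 1e-9) abort("`r0` must not exceed the smaller radius")
  if (r0 == 0) return(Ra + Rb)
  if (abs(Ra - Rb) < 1e-12) return(2 * sqrt(max(Ra^2 - r0^2, 0)))
  half_chord2 <- function(d) {
    xa <- (d^2 + Ra^2 - Rb^2) / (2 * d)
    Ra^2 - xa^2
  }
  lo <- sqrt(abs(Ra^2 - Rb^2)) + 1e-9
  hi <- Ra + Rb - 1e-9
  if (half_chord2(lo) <= r0^2) return(lo)
  uniroot(function(d) half_chord2(d) - r0^2, c(lo, hi), tol = 1e-10)$root
}

render_frame <- function(Ra, Rb, r0, pixel_size, image_shape, angle = 0) {
  d <- if (r0 >= min(Ra, Rb)) {
    if (abs(Ra - Rb) < 1e-9) 0 else doublet_center_distance(min(Ra, Rb) - 1e-9, Ra, Rb)
  } else {
    doublet_center_distance(r0, Ra, Rb)
  }
  nr <- image_shape[1]; nc <- image_shape[2]
  cx <- nc / 2 * pixel_size; cy <- nr / 2 * pixel_size
  ux <- cos(angle); uy <- sin(angle)
  ca <- c(cx - d / 2 * ux, cy - d / 2 * uy)
  cb <- c(cx + d / 2 * ux, cy + d / 2 * uy)
  if (ca[1] - Ra < 0 || ca[2] - Ra < 0 || cb[1] + Rb > nc * pixel_size ||
      cb[2] + Rb > nr * pixel_size || ca[1] + Ra > nc * pixel_size ||
      cb[1] - Rb < 0 || ca[2] + Ra > nr * pixel_size || cb[2] - Rb < 0) {
    abort("doublet does not fit the frame at this pixel size")
  }
  xs <- (seq_len(nc) - 0.5) * pixel_size
  ys <- (seq_len(nr) - 0.5) * pixel_size
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  mask <- ((X - ca[1])^2 + (Y - ca[2])^2 <= Ra^2) |
    ((X - cb[1])^2 + (Y - cb[2])^2 <= Rb^2)
  mask * 1.0
}

#' Render a fusion trajectory as a synthetic doublet image stack
#'
#' Each frame is the binary union of two disks whose radii are the per-frame
#' lobe radii and whose centre distance reproduces the per-frame neck radius
#' through the circle-circle chord relation. This emulates the silhouette a
#' stereomicroscope records of a fusing pair (bright foreground on dark
#' background) without asserting any unmodelled physics.
#'
#' @param series A [neck_series()] with non-missing lobe radii.
#' @param pixel_size Micrometres per pixel.
#' @param image_shape Frame dimensions `c(rows, cols)` in pixels.
#' @param angle Orientation of the doublet axis (radians, default 0).
#' @param on_fused What to do for frames whose neck radius reaches or exceeds
#'   the smaller lobe radius (late fusion, where the rigid two-disk geometry
#'   degenerates): `"single_disk"` renders a fully fused disk — downstream
#'   measurement reports the neck as undefined — and `"error"` aborts.
#' @return A 3-D array `rows x cols x frames` with values 0/1 and attributes
#'   `pixel_size` and `time_h`.
#' @export
render_fusion_frames <- function(series, pixel_size = 1,
                                 image_shape = c(256, 256), angle = 0,
                                 on_fused = c("single_disk", "error")) {
  stopifnot(inherits(series, "neck_series"))
  on_fused <- match.arg(on_fused)
  check_positive(pixel_size, "pixel_size")
  bad <- !series$missing &
    series$neck_radius_um > pmin(series$radius_a_um, series$radius_b_um) + 1e-9
  if (any(bad) && on_fused == "error") {
    abort("neck radius exceeds a lobe radius; cannot render a rigid doublet")
  }
  frames <- array(0, dim = c(image_shape[1], image_shape[2], nrow(series)))
  for (i in seq_len(nrow(series))) {
    r0 <- if (series$missing[i]) 0 else series$neck_radius_um[i]
    r0 <- min(r0, min(series$radius_a_um[i], series$radius_b_um[i]))
    frames[, , i] <- render_frame(series$radius_a_um[i], series$radius_b_um[i],
                                  r0, pixel_size, image_shape, angle)
  }
  structure(frames, pixel_size = pixel_size, time_h = series$time_h)
}

#' Write / read a synthetic image stack as multi-page TIFF
#'
#' 8-bit multi-page TIFF. The calibration (micrometres per pixel and frame
#' times) is written to a plain-text sidecar `<path>.meta` and restored on
#' read; a `pixel_size` argument overrides the sidecar.
#'
#' @param frames Array from [render_fusion_frames()] (or any rows x cols x n
#'   array scaled to `[0, 1]`).
#' @param path Output path.
#' @param pixel_size Micrometres per pixel; defaults to the array attribute.
#' @return `write_frames_tiff()` returns `path` invisibly;
#'   `read_frames_tiff()` returns the array with `pixel_size` and `time_h`
#'   restored when available.
#' @export
write_frames_tiff <- function(frames, path,
                              pixel_size = attr(frames, "pixel_size")) {
  imgs <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  meta <- c(sprintf("pixel_size_um=%.10g", pixel_size))
  times <- attr(frames, "time_h")
  if (!is.null(times)) {
    meta <- c(meta, paste0("time_h=", paste(times, collapse = ",")))
  }
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_frames_tiff
#' @export
read_frames_tiff <- function(path, pixel_size = NULL) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(imgs[[1]])[1], dim(imgs[[1]])[2], length(imgs)))
  for (i in seq_along(imgs)) arr[, , i] <- imgs[[i]]
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    meta <- readLines(meta_path)
    px <- grep("^pixel_size_um=", meta, value = TRUE)
    if (length(px)) {
      attr(arr, "pixel_size") <- as.numeric(sub("^pixel_size_um=", "", px[1]))
    }
    th <- grep("^time_h=", meta, value = TRUE)
    if (length(th)) {
      attr(arr, "time_h") <-
        as.numeric(strsplit(sub("^time_h=", "", th[1]), ",")[[1]])
    }
  }
  if (!is.null(pixel_size)) attr(arr, "pixel_size") <- pixel_size
  arr
}
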