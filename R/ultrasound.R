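#' Synthesize a B-mode-like carotid frame
#'
#' Horizontal-vessel geometry, depth increasing down the image: near-wall
#' tissue, a lumen band at the blood grey level, the far-wall intima-media
#' band of the requested thickness, and adventitia below. The intima-media
#' intensity is the inverse of the grey-scale-median normalization: `blood +
#' (adventitia - blood) * true_gsm / 256`. Band edges are anti-aliased by
#' area sampling so that sub-pixel wall positions are well defined; speckle
#' is emulated as additive Gaussian noise, clipped to [0, 255] and
#' quantized to integer grey levels. Blood and adventitia reference
#' regions and the construction ground truth are recorded.
#'
#' @param true_imt_mm wall thickness (mm, > 0).
#' @param true_gsm target grey-scale median on the 0-256 scale.
#' @param blood_level,adventitia_level reference grey levels in [0, 255],
#'   blood darker than adventitia.
#' @param noise_sd additive noise SD in grey levels.
#' @param seed integer seed (same seed, identical frame).
#' @param mm_per_pixel pixel size (default 0.1 mm).
#' @param depth_mm,width_mm frame extent (default 20 x 12 mm).
#' @param side `"left"` or `"right"` tag.
#' @return An `imio_bmode`: `img` (depth x width integer matrix), scale and
#'   geometry metadata, reference-region masks, ground truth.
#' @export
synth_bmode <- function(true_imt_mm, true_gsm, blood_level = 10,
                        adventitia_level = 190, noise_sd = 6, seed = 1,
                        mm_per_pixel = 0.1, depth_mm = 20, width_mm = 12,
                        side = "left") {
  if (true_imt_mm <= 0) stop("wall thickness must be positive")
  if (blood_level < 0 || adventitia_level > 255 ||
      blood_level >= adventitia_level)
    stop("reference levels must satisfy 0 <= blood < adventitia <= 255")
  if (true_imt_mm < 2 * mm_per_pixel)
    stop("wall thickness below 2 pixels at this resolution")
  nr <- round(depth_mm / mm_per_pixel)
  nc <- round(width_mm / mm_per_pixel)
  lumen_top <- 4
  wall_top <- 10
  wall_bot <- wall_top + true_imt_mm
  if (wall_bot + 2 > depth_mm) stop("far wall outside frame")
  im_level <- blood_level + (adventitia_level - blood_level) * true_gsm / 256
  near_level <- 0.75 * adventitia_level

  # area-sampled (anti-aliased) depth profile, one value per pixel row
  depth0 <- (seq_len(nr) - 1) * mm_per_pixel
  cov <- function(a, b) {
    # coverage of band [a, b) within each pixel [depth0, depth0 + px)
    pmax(pmin(b, depth0 + mm_per_pixel) - pmax(a, depth0), 0) / mm_per_pixel
  }
  profile <- near_level * cov(-1, lumen_top) +
    blood_level * cov(lumen_top, wall_top) +
    im_level * cov(wall_top, wall_bot) +
    adventitia_level * cov(wall_bot, depth_mm + 1)
  img <- matrix(profile, nr, nc)
  img <- with_seed(seed, {
    if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    img
  })
  img <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), nr, nc)

  ref_cols <- seq(5, nc - 5)
  row_at <- function(mm) pmin(pmax(round(mm / mm_per_pixel), 1), nr)
  blood_ref <- cbind(row = rep(seq(row_at(lumen_top + 1), row_at(wall_top - 1)),
                               length(ref_cols)),
                     col = rep(ref_cols,
                               each = row_at(wall_top - 1) -
                                 row_at(lumen_top + 1) + 1))
  adv_ref <- cbind(row = rep(seq(row_at(wall_bot + 0.5), row_at(wall_bot + 2)),
                             length(ref_cols)),
                   col = rep(ref_cols,
                             each = row_at(wall_bot + 2) -
                               row_at(wall_bot + 0.5) + 1))
  structure(list(img = img, mm_per_pixel = mm_per_pixel, side = side,
                 blood_ref = blood_ref, adventitia_ref = adv_ref,
                 lumen_top_mm = lumen_top, wall_top_mm = wall_top,
                 wall_bottom_mm = wall_bot,
                 true_imt_mm = true_imt_mm, true_gsm = true_gsm,
                 blood_level = blood_level,
                 adventitia_level = adventitia_level),
            class = "imio_bmode")
}

#' @export
print.imio_bmode <- function(x, ...) {
  cat(sprintf("B-mode frame %dx%d px (%.2f mm/px, %s side)",
              nrow(x$img), ncol(x$img), x$mm_per_pixel, x$side))
  if (!is.null(x$true_imt_mm))
    cat(sprintf("; ground truth IMT %.2f mm, GSM %.0f",
                x$true_imt_mm, x$true_gsm))
  cat("\n")
  invisible(x)
}

# Sub-pixel 50%-crossing of a rising step around index i0 of profile p:
# linear interpolation between the plateau levels on either side.
halfway_crossing <- function(p, i0, lo_level, hi_level) {
  h <- (lo_level + hi_level) / 2
  # search the crossing in a small neighbourhood of the step
  for (i in seq(max(i0 - 3, 1), min(i0 + 3, length(p) - 1))) {
    if (p[i] <= h && p[i + 1] > h) {
      return(i + (h - p[i]) / (p[i + 1] - p[i]))
    }
  }
  NA_real_
}

# robust plateau level: median over a few pixels on one side of the step
plateau_level <- function(p, idx) {
  idx <- idx[idx >= 1 & idx <= length(p)]
  median(p[idx])
}

#' Detect the far-wall interfaces
#'
#' For each column in a 10 mm window: the lumen-intima interface is the
#' first sufficiently large positive intensity gradient below the lumen
#' centre, and the media-adventitia interface is the maximal gradient below
#' it; both are refined to sub-pixel depth by linear interpolation of the
#' 50% intensity crossing. At 0.1 mm/pixel this yields about 100 discrete
#' measurement columns over the segment.
#'
#' @param frame an `imio_bmode`.
#' @param segment_mm lateral segment length (default 10 mm).
#' @param grad_frac fraction of the column's maximal gradient counted as
#'   suprathreshold for the lumen-intima search.
#' @param smooth half-width of the moving-average profile smoother
#'   (pixels); 0 disables.
#' @param lateral half-width of lateral column averaging (columns).
#' @param max_imt_mm plausible upper bound on wall thickness bounding the
#'   media-adventitia search below the lumen-intima edge.
#' @return An `imio_wall_trace`: per-column `li_mm` and `ma_mm` interface
#'   depths, `n_columns`, `mm_per_pixel`, `side`.
#' @export
detect_far_wall <- function(frame, segment_mm = 10, grad_frac = 0.35,
                            smooth = 1, lateral = 1, max_imt_mm = 2.5) {
  stopifnot(inherits(frame, "imio_bmode"))
  img <- frame$img
  nr <- nrow(img); nc <- ncol(img)
  n_cols <- round(segment_mm / frame$mm_per_pixel)
  if (n_cols > nc) stop("frame narrower than the measurement segment")
  c0 <- floor((nc - n_cols) / 2)
  cols <- c0 + seq_len(n_cols)
  li <- rep(NA_real_, n_cols)
  ma <- rep(NA_real_, n_cols)
  cap_px <- max(4, round(max_imt_mm / frame$mm_per_pixel))
  for (j in seq_along(cols)) {
    # lateral averaging over neighbouring columns suppresses speckle while
    # keeping one measurement per column
    jc <- cols[j] + (-lateral:lateral)
    jc <- jc[jc >= 1 & jc <= nc]
    p <- rowMeans(img[, jc, drop = FALSE])
    if (smooth > 0) {
      kern <- rep(1, 2 * smooth + 1) / (2 * smooth + 1)
      ps <- as.numeric(stats::filter(p, kern, sides = 2))
      ps[is.na(ps)] <- p[is.na(ps)]
      p <- ps
    }
    rng <- range(p)
    if (diff(rng) < 1e-9) next  # constant column: no edges
    lumen <- which.min(p)
    g <- diff(p)
    gmax <- max(g[lumen:(nr - 1)])
    if (gmax <= 0) next
    thr <- grad_frac * gmax
    cand <- which(g[lumen:(nr - 1)] >= thr) + lumen - 1
    if (!length(cand)) next
    i_li <- cand[1]
    # ride the edge to its local gradient peak
    while (i_li + 1 <= nr - 1 && g[i_li + 1] > g[i_li]) i_li <- i_li + 1
    lo <- plateau_level(p, (i_li - 4):(i_li - 2))
    hi <- plateau_level(p, (i_li + 2):(i_li + 4))
    li_px <- halfway_crossing(p, i_li, lo, hi)
    # media-adventitia: maximal gradient below the lumen-intima edge within
    # a plausible wall-thickness window
    below <- seq(min(i_li + 2, nr - 1), min(i_li + cap_px, nr - 1))
    i_ma <- below[which.max(g[below])]
    lo2 <- plateau_level(p, (i_ma - 4):(i_ma - 2))
    hi2 <- plateau_level(p, (i_ma + 2):(i_ma + 4))
    ma_px <- halfway_crossing(p, i_ma, lo2, hi2)
    if (is.na(li_px) || is.na(ma_px) || ma_px <= li_px) next
    li[j] <- li_px * frame$mm_per_pixel
    ma[j] <- ma_px * frame$mm_per_pixel
  }
  ok <- is.finite(li) & is.finite(ma)
  if (mean(!ok) > 0.2)
    stop("far-wall detection failed in more than 20% of columns")
  structure(list(li_mm = li, ma_mm = ma, n_columns = sum(ok),
                 mm_per_pixel = frame$mm_per_pixel, side = frame$side),
            class = "imio_wall_trace")
}

#' @export
print.imio_wall_trace <- function(x, ...) {
  ok <- is.finite(x$li_mm) & is.finite(x$ma_mm)
  cat(sprintf("Far-wall trace (%s): %d columns, mean IMT %.3f mm\n",
              x$side, x$n_columns, mean(x$ma_mm[ok] - x$li_mm[ok])))
  invisible(x)
}

#' Intima-media thickness from left and right wall traces
#'
#' Per side, the mean over measurement columns of (media-adventitia depth -
#' lumen-intima depth); the reported IMT is the mean of the two sides.
#'
#' @param left,right `imio_wall_trace` objects.
#' @return An `imio_imt`: `left_mm`, `right_mm`, `imt_mm`.
#' @export
imt_from_traces <- function(left, right) {
  one <- function(tr) {
    ok <- is.finite(tr$li_mm) & is.finite(tr$ma_mm)
    mean(tr$ma_mm[ok] - tr$li_mm[ok])
  }
  l <- one(left); r <- one(right)
  structure(list(left_mm = l, right_mm = r, imt_mm = (l + r) / 2),
            class = "imio_imt")
}

#' @export
print.imio_imt <- function(x, ...) {
  cat(sprintf("IMT: left %.3f mm, right %.3f mm, mean %.3f mm\n",
              x$left_mm, x$right_mm, x$imt_mm))
  invisible(x)
}

#' Grey-scale median of a region of interest
#'
#' Normalizes the frame linearly so that the median of the blood reference
#' region maps to 0 and the median of the adventitia reference region maps
#' to 256, clamps to [0, 256], and returns the median of the normalized
#' values over the ROI. Invariant under affine intensity transforms of the
#' whole frame, since the references move with it.
#'
#' @param frame an `imio_bmode`.
#' @param roi two-column (row, col) index matrix, or a logical matrix of
#'   the frame's dimensions; defaults to the intima-media band between the
#'   construction interfaces over the central 10 mm.
#' @return An `imio_gsm` with `gsm` plus the reference medians.
#' @export
gsm <- function(frame, roi = NULL) {
  stopifnot(inherits(frame, "imio_bmode"))
  img <- frame$img
  if (is.null(roi)) {
    r0 <- ceiling(frame$wall_top_mm / frame$mm_per_pixel) + 1
    r1 <- floor(frame$wall_bottom_mm / frame$mm_per_pixel)
    if (r1 < r0) stop("degenerate default ROI")
    nc <- ncol(img)
    n_cols <- round(10 / frame$mm_per_pixel)
    cols <- floor((nc - n_cols) / 2) + seq_len(min(n_cols, nc))
    roi <- cbind(row = rep(r0:r1, length(cols)),
                 col = rep(cols, each = r1 - r0 + 1))
  }
  if (is.logical(roi)) roi <- which(roi, arr.ind = TRUE)
  if (!nrow(roi)) stop("empty ROI")
  blood_med <- median(img[frame$blood_ref])
  adv_med <- median(img[frame$adventitia_ref])
  if (adv_med == blood_med)
    stop("reference medians are equal: cannot normalize")
  norm <- 256 * (img[roi] - blood_med) / (adv_med - blood_med)
  norm <- pmin(pmax(norm, 0), 256)
  structure(list(gsm = median(norm), side = frame$side,
                 blood_median = blood_med, adventitia_median = adv_med),
            class = "imio_gsm")
}

#' @export
print.imio_gsm <- function(x, ...) {
  cat(sprintf("GSM (%s): %.1f (refs: blood %.0f, adventitia %.0f)\n",
              x$side, x$gsm, x$blood_median, x$adventitia_median))
  invisible(x)
}

#' Two-side grey-scale median
#'
#' @param left,right `imio_gsm` results.
#' @return List with per-side values and the two-side mean `imgsm`.
#' @export
imgsm_from_sides <- function(left, right) {
  list(left = left$gsm, right = right$gsm,
       imgsm = (left$gsm + right$gsm) / 2)
}

#' Measure one frame end to end
#'
#' Far-wall detection followed by thickness averaging and grey-scale-median
#' extraction with the detected band as ROI.
#'
#' @param frame an `imio_bmode`.
#' @return List with `trace`, `imt_mm` (single-side mean thickness), `gsm`.
#' @export
measure_frame <- function(frame) {
  tr <- detect_far_wall(frame)
  ok <- is.finite(tr$li_mm) & is.finite(tr$ma_mm)
  imt <- mean(tr$ma_mm[ok] - tr$li_mm[ok])
  # ROI: detected band, per column, one pixel inside each interface
  rows <- lapply(which(ok), function(j) {
    r0 <- ceiling(tr$li_mm[j] / frame$mm_per_pixel) + 1
    r1 <- floor(tr$ma_mm[j] / frame$mm_per_pixel)
    if (r1 < r0) return(NULL)
    cbind(row = r0:r1, col = j + floor((ncol(frame$img) -
                                          length(tr$li_mm)) / 2))
  })
  roi <- do.call(rbind, rows)
  g <- gsm(frame, roi)
  list(trace = tr, imt_mm = imt, gsm = g)
}

#' Write / read a B-mode frame as PNG with a JSON sidecar
#'
#' The PNG stores the 8-bit grey image; the sidecar records the scale,
#' reference-region boxes and ground truth.
#'
#' @param frame an `imio_bmode`.
#' @param png_path,json_path output paths.
#' @export
write_bmode <- function(frame, png_path,
                        json_path = sub("\\.png$", ".json", png_path)) {
  png::writePNG(frame$img / 255, png_path)
  meta <- frame[setdiff(names(frame), "img")]
  meta$blood_ref <- as.data.frame(frame$blood_ref)
  meta$adventitia_ref <- as.data.frame(frame$adventitia_ref)
  jsonlite::write_json(meta, json_path, digits = NA, auto_unbox = TRUE)
  invisible(png_path)
}

#' @rdname write_bmode
#' @export
read_bmode <- function(png_path,
                       json_path = sub("\\.png$", ".json", png_path)) {
  img <- png::readPNG(png_path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  meta$img <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  meta$blood_ref <- as.matrix(meta$blood_ref)
  meta$adventitia_ref <- as.matrix(meta$adventitia_ref)
  structure(meta[c("img", setdiff(names(meta), "img"))],
            class = "imio_bmode")
}
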