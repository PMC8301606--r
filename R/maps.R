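#' Build a voxel series from per-subject reference-space maps
#'
#' Stacks per-subject reference-space volumes (one channel: Jacobian local
#' volume, or fat content pulled to reference space) into a subjects x
#' voxels matrix aligned with the cohort row order.
#'
#' @param maps named list of `imio_volume`s on the reference grid, names =
#'   subject ids.
#' @param cohort an `imio_cohort`; `names(maps)` must equal `cohort$id` in
#'   order.
#' @param channel channel tag, `"volume"` or `"fat"`.
#' @return An `imio_series`: list with `X` (subjects x voxels matrix),
#'   `dim`, `spacing`, `channel`, `ids`.
#' @export
build_voxel_series <- function(maps, cohort, channel = c("volume", "fat")) {
  channel <- match.arg(channel)
  if (!length(maps)) stop("no maps supplied")
  if (is.null(names(maps)) || !identical(names(maps), as.character(cohort$id)))
    stop("map names must match cohort ids in order")
  d <- dim(maps[[1]]$data)
  for (m in maps) check_same_grid(maps[[1]], m)
  X <- do.call(rbind, lapply(maps, function(m) as.numeric(m$data)))
  structure(list(X = X, dim = d, spacing = maps[[1]]$spacing,
                 channel = channel, ids = names(maps)),
            class = "imio_series")
}

#' @export
print.imio_series <- function(x, ...) {
  cat(sprintf("Voxel series [%s]: %d subjects x %s grid\n", x$channel,
              nrow(x$X), paste(x$dim, collapse = "x")))
  invisible(x)
}

new_corr_map <- function(coef, p, n, d, spacing, method, trait, channel) {
  structure(list(coef = array(coef, d), p = array(p, d),
                 n = array(n, d), spacing = spacing, method = method,
                 trait = trait, channel = channel),
            class = "imio_map")
}

#' Voxel-wise Spearman correlation map
#'
#' For every voxel, the Spearman rank coefficient between the subject
#' series and a per-subject scalar trait: values are average-rank
#' transformed (ties averaged) and Pearson-correlated; the two-sided
#' p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` with
#' n-2 degrees of freedom. Subjects with a missing value at a voxel are
#' dropped voxel-wise (listwise) and the n used is recorded; degenerate
#' (constant) voxels give `NaN` coefficient and p.
#'
#' @param series an `imio_series`.
#' @param y numeric trait, one value per subject.
#' @param trait trait tag stored in the map.
#' @return An `imio_map` with per-voxel `coef`, `p` and `n`.
#' @export
spearman_map <- function(series, y, trait = deparse(substitute(y))) {
  stopifnot(inherits(series, "imio_series"))
  n <- nrow(series$X)
  if (n < 4) stop("at least 4 subjects are required")
  if (length(y) != n) stop("trait length must equal subject count")
  res <- spearman_cols_cpp(series$X, as.numeric(y))
  rho <- res$rho
  nn <- res$n
  p <- rep(NaN, length(rho))
  ok <- is.finite(rho) & nn >= 4
  tstat <- rho[ok] * sqrt((nn[ok] - 2) / pmax(1 - rho[ok]^2, 1e-300))
  p[ok] <- 2 * pt(-abs(tstat), df = nn[ok] - 2)
  rho[!ok] <- NaN
  new_corr_map(rho, p, nn, series$dim, series$spacing, "spearman",
               trait, series$channel)
}

#' Voxel-wise partial (parametric) correlation map
#'
#' Pearson partial correlation of each voxel series with a trait,
#' controlling for a single confounder (e.g. a composite cardiovascular
#' risk score): `r_xy.z = (r_xy - r_xz r_zy) / sqrt((1-r_xz^2)(1-r_zy^2))`,
#' with the two-sided p-value from a t statistic on n-3 degrees of freedom.
#' Voxels where the confounder is collinear with the series (`|r_xz| = 1`)
#' give `NaN`.
#'
#' @param series an `imio_series`.
#' @param y numeric trait per subject.
#' @param z numeric confounder per subject.
#' @param trait trait tag stored in the map.
#' @return An `imio_map`.
#' @export
partial_corr_map <- function(series, y, z, trait = deparse(substitute(y))) {
  stopifnot(inherits(series, "imio_series"))
  n <- nrow(series$X)
  if (n < 5) stop("at least 5 subjects are required")
  if (length(y) != n || length(z) != n)
    stop("trait and confounder must have one value per subject")
  if (!all(is.finite(y)) || !all(is.finite(z)))
    stop("trait and confounder must be finite")
  X <- series$X
  # complete rows only (voxel series may carry NA; partial correlation is
  # computed on rows complete for that voxel)
  col_ok <- colSums(!is.finite(X)) == 0
  rho <- rep(NaN, ncol(X))
  nn <- rep(0L, ncol(X))
  if (any(col_ok)) {
    Xc <- X[, col_ok, drop = FALSE]
    cx <- scale(Xc, center = TRUE, scale = FALSE)
    sy <- y - mean(y)
    sz <- z - mean(z)
    ssx <- colSums(cx^2)
    r_xy <- as.numeric(crossprod(cx, sy)) / sqrt(ssx * sum(sy^2))
    r_xz <- as.numeric(crossprod(cx, sz)) / sqrt(ssx * sum(sz^2))
    r_zy <- sum(sz * sy) / sqrt(sum(sz^2) * sum(sy^2))
    denom <- (1 - r_xz^2) * (1 - r_zy^2)
    r <- (r_xy - r_xz * r_zy) / sqrt(pmax(denom, 0))
    r[!is.finite(r) | denom <= 1e-14] <- NaN
    r <- pmin(pmax(r, -1), 1)
    rho[col_ok] <- r
    nn[col_ok] <- n
  }
  p <- rep(NaN, length(rho))
  ok <- is.finite(rho)
  tstat <- rho[ok] * sqrt((n - 3) / pmax(1 - rho[ok]^2, 1e-300))
  p[ok] <- 2 * pt(-abs(tstat), df = n - 3)
  new_corr_map(rho, p, nn, series$dim, series$spacing, "partial",
               trait, series$channel)
}

#' @export
print.imio_map <- function(x, ...) {
  ok <- is.finite(x$coef)
  cat(sprintf(
    "%s correlation map [%s ~ %s]: %s grid, %.1f%% voxels defined, %.1f%% p<0.05\n",
    x$method, x$channel, x$trait, paste(dim(x$coef), collapse = "x"),
    100 * mean(ok), 100 * mean(x$p[ok] < 0.05)))
  invisible(x)
}

#' @export
summary.imio_map <- function(object, alpha = 0.05, ...) {
  ok <- is.finite(object$coef)
  sig <- ok & object$p < alpha
  list(n_voxels = sum(ok), n_significant = sum(sig),
       frac_significant = mean(sig[ok]),
       coef_range = range(object$coef[ok]),
       strongest_positive = suppressWarnings(max(object$coef[sig], na.rm = TRUE)),
       strongest_negative = suppressWarnings(min(object$coef[sig], na.rm = TRUE)))
}

#' Suppress small significant clusters
#'
#' Operational counterpart of reporting only associations covering many
#' image elements within an anatomical structure: 26-connected components
#' of suprathreshold (p < alpha) voxels smaller than `min_voxels` have
#' their p-values set to 1 (coefficients untouched), so they render as
#' non-significant.
#'
#' @param map an `imio_map`.
#' @param min_voxels minimum component size retained (default 50).
#' @param alpha significance threshold defining suprathreshold voxels.
#' @return The filtered `imio_map`.
#' @export
cluster_filter <- function(map, min_voxels = 50, alpha = 0.05) {
  stopifnot(inherits(map, "imio_map"))
  if (min_voxels < 1) stop("min_voxels must be >= 1")
  if (min_voxels == 1) return(map)
  sig <- is.finite(map$p) & map$p < alpha
  if (!any(sig)) return(map)
  lab <- label_components26_cpp(as.logical(sig), as.integer(dim(map$p)))
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_voxels)
  if (length(small)) {
    drop <- array(lab, dim(map$p)) %in% small
    map$p[drop] <- 1
  }
  map
}

# Reversed jet colormap lookup: coefficient in [-1, 1] -> RGB in [0, 1];
# red at +1 (strong positive), blue at -1.
jet_inverted <- function(v) {
  v <- pmin(pmax(v, -1), 1)
  # classic jet on [0, 1] runs blue -> cyan -> yellow -> red; map +1 to the
  # red end by taking t = (v + 1) / 2
  t <- (v + 1) / 2
  r <- pmin(pmax(1.5 - abs(4 * t - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * t - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * t - 1), 0), 1)
  cbind(r, g, b)
}

#' Render a correlation map in the standard layout
#'
#' One coronal and six axial slices: voxels with p >= alpha (or undefined)
#' show the grey water-signal underlay; significant voxels show the
#' coefficient under the reversed-jet colormap with a fixed [-1, 1] range
#' (red = strong positive, blue = strong negative). Returns the RGB raster
#' and optionally writes a PNG with a colorbar strip.
#'
#' @param map an `imio_map`.
#' @param underlay `imio_volume` on the same grid (water signal).
#' @param alpha transparency threshold (default 0.05).
#' @param coronal_y index of the coronal slice (default mid-grid).
#' @param axial_z indices of the six axial slices (default spread over the
#'   grid).
#' @param path optional PNG output path.
#' @return Invisibly, the RGB array (height x width x 3, values in [0,1]).
#' @export
render_map <- function(map, underlay, alpha = 0.05, coronal_y = NULL,
                       axial_z = NULL, path = NULL) {
  stopifnot(inherits(map, "imio_map"), inherits(underlay, "imio_volume"))
  if (!identical(dim(map$coef), dim(underlay$data)))
    stop("map and underlay are not on the same grid")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  d <- dim(map$coef)
  if (is.null(coronal_y)) coronal_y <- round(d[2] / 2)
  if (is.null(axial_z))
    axial_z <- round(seq(0.15, 0.8, length.out = 6) * d[3])
  if (coronal_y < 1 || coronal_y > d[2] || any(axial_z < 1 | axial_z > d[3]))
    stop("slice index out of range")
  un <- underlay$data
  rng <- range(un)
  grey <- if (diff(rng) > 0) (un - rng[1]) / diff(rng) else un * 0

  paint_slice <- function(coefs, ps, greys) {
    # returns h x w x 3
    sig <- is.finite(coefs) & is.finite(ps) & ps < alpha
    rgb <- array(rep(greys, 3), c(dim(greys), 3))
    if (any(sig)) {
      cols <- jet_inverted(coefs[sig])
      for (k in 1:3) {
        ch <- rgb[, , k]
        ch[sig] <- cols[, k]
        rgb[, , k] <- ch
      }
    }
    rgb
  }
  # coronal: x-z plane at fixed y; display with head up
  flipz <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  cor_rgb <- paint_slice(flipz(map$coef[, coronal_y, ]),
                         flipz(map$p[, coronal_y, ]),
                         flipz(grey[, coronal_y, ]))
  ax_rgb <- lapply(axial_z, function(z)
    paint_slice(map$coef[, , z], map$p[, , z], grey[, , z]))

  # montage: coronal on the left, axial slices stacked 2 x 3 on the right,
  # colorbar strip at the far right
  h <- dim(cor_rgb)[2]
  ax_h <- d[2]; ax_w <- d[1]
  rows <- 3; cols_n <- 2
  pane_h <- max(h, rows * ax_h)
  bar_w <- 12
  W <- dim(cor_rgb)[1] + cols_n * ax_w + bar_w + 4
  img <- array(0, c(W, pane_h, 3))
  img[seq_len(dim(cor_rgb)[1]), seq_len(h), ] <- cor_rgb
  for (i in seq_along(ax_rgb)) {
    r <- (i - 1) %% rows; cidx <- (i - 1) %/% rows
    x0 <- dim(cor_rgb)[1] + cidx * ax_w
    y0 <- r * ax_h
    img[x0 + seq_len(ax_w), y0 + seq_len(ax_h), ] <- ax_rgb[[i]]
  }
  bar_vals <- seq(1, -1, length.out = pane_h)
  bar <- jet_inverted(bar_vals)
  for (k in 1:3)
    img[W - bar_w + seq_len(bar_w), , k] <-
      matrix(rep(bar[, k], each = bar_w), bar_w, pane_h)
  # to raster orientation (rows = y from top)
  out <- aperm(img, c(2, 1, 3))[rev(seq_len(pane_h)), , , drop = FALSE]
  if (!is.null(path)) png::writePNG(pmin(pmax(out, 0), 1), path)
  invisible(out)
}

#' @export
plot.imio_map <- function(x, underlay, ...) {
  rgb <- render_map(x, underlay, ...)
  op <- graphics::par(mar = c(0, 0, 2, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(rgb), 0, 0, 1, 1)
  graphics::title(sprintf("%s ~ %s (%s)", x$channel, x$trait, x$method))
  invisible(x)
}

#' Write a correlation map as a NIfTI pair
#'
#' @param map an `imio_map`.
#' @param coef_path,p_path output paths for the coefficient and p-value
#'   volumes.
#' @export
write_map <- function(map, coef_path, p_path) {
  write_volume(imio_volume(map$coef, map$spacing), coef_path)
  write_volume(imio_volume(map$p, map$spacing), p_path)
  invisible(c(coef_path, p_path))
}
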