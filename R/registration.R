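#' Tissue masks for the sequential registration
#'
#' Bone, lean (water-dominated) and fat masks on a shared grid. With a label
#' volume (the synthetic path) bone is taken from the bone label; otherwise
#' an intensity rule is used (low fat and low water inside the body). The
#' fat mask is fat fraction >= 0.5; lean tissue is the remaining body.
#'
#' @param fat,water `imio_volume`s on the same grid (fat as fraction).
#' @param labels optional integer label `imio_volume`.
#' @param body_threshold minimum fat+water signal counted as body.
#' @return An `imio_masks` list with logical arrays `bone`, `lean`, `fat`,
#'   `body`.
#' @export
segment_tissues <- function(fat, water, labels = NULL,
                            body_threshold = 0.2) {
  check_same_grid(fat, water)
  body <- fat$data + water$data >= body_threshold
  if (!is.null(labels)) {
    check_same_grid(fat, labels)
    bone <- labels$data == .imio_label_codes[["bone"]]
    body <- body | labels$data > 0
  } else {
    bone <- body & fat$data < 0.25 & water$data < 0.5
  }
  fatmask <- body & fat$data >= 0.5 & !bone
  lean <- body & !bone & !fatmask
  structure(list(bone = bone, lean = lean, fat = fatmask, body = body,
                 spacing = fat$spacing),
            class = "imio_masks")
}

#' @export
print.imio_masks <- function(x, ...) {
  cat(sprintf("Tissue masks: body %d, bone %d, lean %d, fat %d voxels\n",
              sum(x$body), sum(x$bone), sum(x$lean), sum(x$fat)))
  invisible(x)
}

# Partition a bone mask into articulated segments by normalized geometry:
# skull above the shoulders, arms lateral at trunk height, spine central,
# pelvis at the hip band, legs below, split left/right.
bone_segments <- function(bone, spacing) {
  d <- dim(bone)
  idx <- which(bone, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty bone mask")
  # bands as fractions of the full grid extent, identical for reference and
  # subject masks sharing the grid
  L <- (d - 1) * spacing
  z <- (idx[, 3] - 1) * spacing[3] / L[3]
  x <- ((idx[, 1] - 1) * spacing[1] - L[1] / 2) / L[1]
  seg <- character(nrow(idx))
  seg[z >= 0.85] <- "skull"
  trunk <- z >= 0.50 & z < 0.85
  seg[trunk & abs(x) <= 0.27] <- "spine"
  seg[trunk & x < -0.27] <- "arm_left"
  seg[trunk & x > 0.27] <- "arm_right"
  seg[z >= 0.415 & z < 0.50] <- "pelvis"
  legs <- z < 0.415
  seg[legs & x <= 0] <- "leg_left"
  seg[legs & x > 0] <- "leg_right"
  masks <- list()
  for (s in unique(seg)) {
    m <- array(FALSE, d)
    m[idx[seg == s, , drop = FALSE]] <- TRUE
    masks[[s]] <- m
  }
  masks
}

# Moment-matching affine (axis-aligned scale + translation) from one mask
# to another, in mm: maps reference-segment points to subject points.
moment_affine <- function(ref_mask, subj_mask, spacing) {
  stats_of <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    P <- sweep(idx - 1, 2, spacing, `*`)
    list(n = nrow(idx), mu = colMeans(P), sd = apply(P, 2, sd))
  }
  r <- stats_of(ref_mask); s <- stats_of(subj_mask)
  # axes whose second moments are too small for a stable ratio (thin limb
  # bones) fall back to scale 1; estimated scales are capped at
  # anatomically plausible bounds
  scale <- c(1, 1, 1)
  if (r$n >= 20 && s$n >= 20) {
    ok <- r$sd >= 0.6 * spacing & s$sd >= 0.6 * spacing
    scale[ok] <- pmin(pmax(s$sd[ok] / r$sd[ok], 2 / 3), 1.5)
  }
  list(scale = scale, ref_center = r$mu, subj_center = s$mu)
}

apply_segment_affine <- function(aff, P) {
  sweep(sweep(P, 2, aff$ref_center), 2, aff$scale, `*`) +
    matrix(aff$subj_center, nrow(P), 3, byrow = TRUE)
}

# SSD-based refinement of a segment affine on smoothed, downsampled masks.
refine_affine <- function(aff, ref_mask, subj_mask, spacing, maxit = 15) {
  d <- dim(ref_mask)
  ds <- pmax(1L, as.integer(round(d / 2)))
  rs <- resample_volume(imio_volume(ref_mask * 1, spacing), ds)
  ss <- resample_volume(imio_volume(subj_mask * 1, spacing), ds)
  rs <- smooth_volume(rs, 1); ss <- smooth_volume(ss, 1)
  cc <- coord_arrays(ds, rs$spacing)
  P <- cbind(as.numeric(cc$X), as.numeric(cc$Y), as.numeric(cc$Z))
  keep <- as.numeric(rs$data) > 0.05
  if (sum(keep) < 10) return(aff)
  P <- P[keep, , drop = FALSE]
  rv <- as.numeric(rs$data)[keep]
  obj <- function(par) {
    a <- list(scale = exp(par[1:3]), ref_center = aff$ref_center,
              subj_center = aff$subj_center + par[4:6])
    Q <- apply_segment_affine(a, P)
    qx <- Q[, 1] / ss$spacing[1]; qy <- Q[, 2] / ss$spacing[2]
    qz <- Q[, 3] / ss$spacing[3]
    sv <- trilinear_at(ss$data, qx, qy, qz)
    mean((sv - rv)^2)
  }
  fit <- tryCatch(
    stats::optim(c(log(aff$scale), c(0, 0, 0)), obj,
                 method = "Nelder-Mead", control = list(maxit = maxit)),
    error = function(e) NULL)
  if (is.null(fit)) return(aff)
  list(scale = exp(fit$par[1:3]), ref_center = aff$ref_center,
       subj_center = aff$subj_center + fit$par[4:6])
}

# Trilinear interpolation of a 3-D array at fractional voxel coordinates.
trilinear_at <- function(arr, qx, qy, qz) {
  d <- dim(arr)
  x0 <- pmin(pmax(floor(qx), 0), d[1] - 1); x1 <- pmin(x0 + 1, d[1] - 1)
  y0 <- pmin(pmax(floor(qy), 0), d[2] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z0 <- pmin(pmax(floor(qz), 0), d[3] - 1); z1 <- pmin(z0 + 1, d[3] - 1)
  fx <- pmin(pmax(qx - x0, 0), 1); fy <- pmin(pmax(qy - y0, 0), 1)
  fz <- pmin(pmax(qz - z0, 0), 1)
  at <- function(ix, iy, iz) arr[cbind(ix + 1, iy + 1, iz + 1)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x1, y0, z0)) +
              fy * ((1 - fx) * at(x0, y1, z0) + fx * at(x1, y1, z0))) +
    fz * ((1 - fy) * ((1 - fx) * at(x0, y0, z1) + fx * at(x1, y0, z1)) +
          fy * ((1 - fx) * at(x0, y1, z1) + fx * at(x1, y1, z1)))
}

#' Articulated piece-wise affine bone registration
#'
#' Partitions the reference bone mask into predefined segments (skull,
#' spine, pelvis, left/right arm, left/right leg), estimates one
#' axis-aligned affine per segment by moment matching (centroid and
#' per-axis second moments) with optional SSD refinement on smoothed masks,
#' and blends the segment affines into a single smooth displacement field
#' with normalized Gaussian weights centred on the segment masks.
#'
#' @param ref,subj `imio_masks` (only the bone masks are used).
#' @param refine run the SSD refinement step (default TRUE).
#' @param blend_sigma Gaussian blending bandwidth in voxels.
#' @param anchor weight of the identity transform in the blending, so
#'   displacements decay to zero away from bone.
#' @return List of class `imio_bone_reg`: `affines` (per segment),
#'   `field` (blended `imio_field`), `segments` (reference segment masks).
#' @export
register_bones <- function(ref, subj, refine = TRUE, blend_sigma = 3,
                           anchor = 0.02) {
  if (!sum(ref$bone) || !sum(subj$bone))
    stop("empty bone mask: cannot register bones")
  spacing <- ref$spacing
  d <- dim(ref$bone)
  ref_segs <- bone_segments(ref$bone, spacing)
  subj_segs <- bone_segments(subj$bone, spacing)
  common <- intersect(names(ref_segs), names(subj_segs))
  affines <- list()
  for (s in common) {
    aff <- moment_affine(ref_segs[[s]], subj_segs[[s]], spacing)
    if (refine) aff <- refine_affine(aff, ref_segs[[s]], subj_segs[[s]],
                                     spacing)
    affines[[s]] <- aff
  }
  # blended field: normalized Gaussian bump weights from segment masks
  cc <- coord_arrays(d, spacing)
  P <- cbind(as.numeric(cc$X), as.numeric(cc$Y), as.numeric(cc$Z))
  # identity anchor: far from every segment the field decays to zero
  wsum <- array(anchor, d)
  ux <- array(0, d); uy <- array(0, d); uz <- array(0, d)
  for (s in common) {
    w <- smooth3_cpp(as.numeric(ref_segs[[s]] * 1), as.integer(d),
                     rep(blend_sigma, 3))
    Q <- apply_segment_affine(affines[[s]], P)
    ux <- ux + array(w * (Q[, 1] - P[, 1]), d)
    uy <- uy + array(w * (Q[, 2] - P[, 2]), d)
    uz <- uz + array(w * (Q[, 3] - P[, 3]), d)
    wsum <- wsum + array(w, d)
  }
  u <- array(c(ux / wsum, uy / wsum, uz / wsum), c(d, 3))
  structure(list(affines = affines,
                 field = imio_field(u, spacing),
                 segments = ref_segs),
            class = "imio_bone_reg")
}

#' @export
print.imio_bone_reg <- function(x, ...) {
  cat("Articulated bone registration,", length(x$affines), "segments\n")
  for (s in names(x$affines)) {
    a <- x$affines[[s]]
    cat(sprintf("  %-10s scale (%.3f, %.3f, %.3f), det %.3f\n", s,
                a$scale[1], a$scale[2], a$scale[3], prod(a$scale)))
  }
  invisible(x)
}

#' Constrained multi-resolution demons registration
#'
#' Second and third stage of the tissue-sequential scheme: a demons-style
#' intensity registration of one image channel, initialized at a constraint
#' field and with the constrained tissue frozen to it. The water stage
#' (`stage = "water"`) registers the water channel with bone frozen and
#' stronger update smoothing ("semi-elastic"); the fat stage
#' (`stage = "fat"`) registers the fat channel with bone and lean tissue
#' frozen and lighter smoothing ("elastic"). Multi-resolution (x4, x2, x1 by
#' default), early stop when the mean update drops below `stop_tol` voxels;
#' a level's iterations are rolled back with a warning if they drive the
#' Jacobian non-positive inside the body.
#'
#' @param ref,subj `imio_volume`s of the stage's channel (reference and
#'   subject).
#' @param stage `"water"` or `"fat"`.
#' @param constraint reference-to-subject `imio_field` to initialize from
#'   and freeze to (bone field for the water stage; the composed bone+water
#'   field for the fat stage).
#' @param masks reference `imio_masks` defining the frozen tissue.
#' @param levels integer downsampling factors, coarse to fine.
#' @param iters maximum iterations, recycled per level (coarse to fine).
#' @param sigma Gaussian smoothing of the update field, in in-plane voxels
#'   of each level and applied isotropically in mm (the per-axis voxel
#'   bandwidth is scaled by the spacing ratio); default 2 (water,
#'   semi-elastic) or 1 (fat, elastic).
#' @param sigma_total Gaussian smoothing of the accumulated field each
#'   iteration (diffusion-like regularization, same units as `sigma`);
#'   propagates boundary displacements into homogeneous region interiors.
#' @param img_sigma Gaussian pre-smoothing of both image channels at each
#'   level (same units), extending gradient support beyond tissue edges.
#' @param stop_tol mean-update early-stop threshold (voxels).
#' @param step_max maximum per-iteration step in voxels.
#' @return The total `imio_field` (constraint plus elastic increment),
#'   equal to the constraint exactly on the frozen mask.
#' @export
register_elastic <- function(ref, subj, stage = c("water", "fat"),
                             constraint = NULL, masks = NULL,
                             levels = c(4, 2, 1), iters = 50,
                             sigma = NULL, sigma_total = 0.5,
                             img_sigma = 1, stop_tol = 0.01,
                             step_max = 1) {
  stage <- match.arg(stage)
  check_same_grid(ref, subj)
  d <- dim(ref$data)
  if (is.null(constraint)) constraint <- zero_field(d, ref$spacing)
  check_same_grid(ref, constraint, "volume and constraint field")
  if (is.null(sigma)) sigma <- if (stage == "water") 2 else 1
  if (sigma <= 0) stop("regularization sigma must be positive")
  frozen_full <- if (is.null(masks)) array(FALSE, d)
  else if (stage == "water") masks$bone else (masks$bone | masks$lean)

  u <- constraint$u
  iters <- rep_len(iters, length(levels))
  for (li in seq_along(levels)) {
    lev <- levels[li]
    ld <- pmax(as.integer(round(d / lev)), 4L)
    refL <- resample_volume(ref, ld)
    subjL <- resample_volume(subj, ld)
    spacingL <- refL$spacing
    # bandwidths are given in in-plane voxels of the level and converted
    # per axis so the smoothing is isotropic in mm at that level
    iso <- spacingL[1] / spacingL
    if (img_sigma > 0) {
      refL <- smooth_volume(refL, img_sigma * iso)
      subjL <- smooth_volume(subjL, img_sigma * iso)
    }
    uL <- resample_field(imio_field(u, ref$spacing), ld)$u
    constrL <- resample_field(constraint, ld)$u
    frozenL <- array(resample3_cpp(as.numeric(frozen_full * 1),
                                   as.integer(d), as.integer(ld), 1L) > 0.5,
                     ld)
    uL_num <- demons_level_cpp(
      as.numeric(refL$data), as.numeric(subjL$data), as.numeric(uL),
      as.numeric(constrL), as.logical(frozenL), as.integer(ld), spacingL,
      as.integer(iters[li]), sigma * iso,
      sigma_total * iso, step_max, stop_tol)
    uL <- array(uL_num, c(ld, 3))
    u_new <- resample_field(imio_field(uL, spacingL), d)$u
    jl <- jacobian_cpp(as.numeric(u_new), as.integer(d), ref$spacing)
    body <- as.numeric(ref$data) > 0.05
    if (any(jl[body] <= 0)) {
      warning("level ", lev,
              ": update produced non-positive Jacobian; level rejected")
    } else {
      u <- u_new
    }
  }
  # bone-constraint exactness, bit-exact on the frozen mask
  if (any(frozen_full)) {
    for (c in 1:3) {
      uc <- u[, , , c]; cc0 <- constraint$u[, , , c]
      uc[frozen_full] <- cc0[frozen_full]
      u[, , , c] <- uc
    }
  }
  imio_field(u, ref$spacing)
}

#' Full tissue-sequential registration of a subject to the reference
#'
#' Runs the three stages in order: articulated piece-wise affine bone
#' registration, semi-elastic water registration constrained on bone, and
#' elastic fat registration constrained on bone and water; returns the
#' final reference-to-subject field and its Jacobian map.
#'
#' @param ref_phantom,subj_phantom `imio_phantom`-like lists with `fat`,
#'   `water`, `labels` volumes.
#' @param iters,levels forwarded to [register_elastic()].
#' @param refine_bones forwarded to [register_bones()].
#' @return List with `field` (`imio_field`), `jacobian` (`imio_volume`),
#'   `bone` (the `imio_bone_reg`).
#' @export
register_subject <- function(ref_phantom, subj_phantom, iters = c(60, 40, 20),
                             levels = c(4, 2, 1), refine_bones = TRUE,
                             sigma_total = 0.5) {
  ref_masks <- segment_tissues(ref_phantom$fat, ref_phantom$water,
                               ref_phantom$labels)
  subj_masks <- segment_tissues(subj_phantom$fat, subj_phantom$water,
                                subj_phantom$labels)
  bone <- register_bones(ref_masks, subj_masks, refine = refine_bones)
  fwater <- register_elastic(ref_phantom$water, subj_phantom$water,
                             "water", constraint = bone$field,
                             masks = ref_masks, levels = levels,
                             iters = iters, sigma_total = sigma_total)
  ffat <- register_elastic(ref_phantom$fat, subj_phantom$fat, "fat",
                           constraint = fwater, masks = ref_masks,
                           levels = levels, iters = iters,
                           sigma_total = sigma_total)
  list(field = ffat, jacobian = jacobian_map(ffat), bone = bone)
}
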