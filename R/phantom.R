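# Region label codes of the phantom body.
.imio_label_codes <- c(
  background = 0L, bone = 1L, leg_muscle = 2L, arm_muscle = 3L,
  liver = 4L, pancreas = 5L, heart_blood = 6L, vat = 7L,
  sat_upper = 8L, sat_lower = 9L, other_lean = 10L
)

#' Phantom region label codes
#' @return Named integer vector of region codes used in label volumes.
#' @export
imio_labels <- function() .imio_label_codes

# Regions whose size can be rescaled per subject.
.imio_scalable <- c("leg_muscle", "arm_muscle", "vat", "sat_upper",
                    "sat_lower", "liver", "heart_blood")

.imio_default_ff <- c(
  background = 0, bone = 0.15, leg_muscle = 0.08, arm_muscle = 0.08,
  liver = 0.05, pancreas = 0.05, heart_blood = 0.02, vat = 0.85,
  sat_upper = 0.9, sat_lower = 0.9, other_lean = 0.15
)

#' Specify one body phantom
#'
#' Per-region size scale factors (relative to the reference body) and
#' fat-fraction levels, plus the image grid. The default grid is 128 x 96 x
#' 250 voxels at 4 x 4 x 8 mm (left-right x anterior-posterior x foot-head);
#' the in-plane spacing is deliberately coarser than a clinical whole-body
#' protocol (about 2 x 2 x 8 mm) to keep desk-scale runtimes, and is fully
#' configurable. Adipose depots (VAT, SAT) must keep fat fraction >= 0.5 so
#' that fat-content thresholding retains them by construction.
#'
#' @param scales named numeric vector of per-region scale factors in
#'   `[0.5, 2]` for a subset of
#'   leg_muscle/arm_muscle/vat/sat_upper/sat_lower/liver/heart_blood.
#' @param ff named fat-fraction levels in `[0, 1]` overriding the defaults.
#' @param shape grid dimensions (voxels).
#' @param spacing voxel spacing (mm, > 0).
#' @param noise_sd SD of additive Gaussian fat-fraction noise (fraction).
#' @return An `imio_phantom_spec`.
#' @export
phantom_spec <- function(scales = NULL, ff = NULL,
                         shape = c(128L, 96L, 250L),
                         spacing = c(4, 4, 8), noise_sd = 0.02) {
  sc <- setNames(rep(1, length(.imio_scalable)), .imio_scalable)
  if (!is.null(scales)) {
    bad <- setdiff(names(scales), .imio_scalable)
    if (length(bad)) stop("unknown scalable regions: ",
                          paste(bad, collapse = ", "))
    sc[names(scales)] <- scales
  }
  if (any(sc < 0.5 | sc > 2))
    stop("region scale factors must lie in [0.5, 2]")
  levels <- .imio_default_ff
  if (!is.null(ff)) {
    bad <- setdiff(names(ff), names(levels))
    if (length(bad)) stop("unknown regions in ff: ",
                          paste(bad, collapse = ", "))
    levels[names(ff)] <- ff
  }
  if (any(levels < 0 | levels > 1)) stop("fat fractions must lie in [0, 1]")
  if (any(levels[c("vat", "sat_upper", "sat_lower")] < 0.5))
    stop("adipose depot fat fractions must be >= 0.5")
  if (length(spacing) != 3 || any(spacing <= 0)) stop("spacing must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(scales = sc, ff = levels,
                 shape = as.integer(shape), spacing = as.numeric(spacing),
                 noise_sd = noise_sd),
            class = "imio_phantom_spec")
}

# Geometry of the reference body, in mm, parameterized by the physical
# grid extents so that coarser test grids cover the same anatomy.
phantom_geometry <- function(shape, spacing) {
  L <- shape * spacing
  Lx <- L[1]; Ly <- L[2]; Lz <- L[3]
  xc <- Lx / 2; yc <- Ly / 2
  list(
    Lx = Lx, Ly = Ly, Lz = Lz, xc = xc, yc = yc,
    leg_x = c(xc - 0.17 * Lx, xc + 0.17 * Lx),
    leg_zmax = 0.46 * Lz,
    leg_r_ankle = 0.09 * Lx, leg_r_hip = 0.14 * Lx,
    leg_bone_r = 0.035 * Lx,
    torso_z = c(0.45, 0.83) * Lz,
    torso_a = 0.35 * Lx, torso_b = 0.31 * Ly,
    sat_upper_frac = 0.82,
    arm_x = c(xc - 0.40 * Lx, xc + 0.40 * Lx),
    arm_z = c(0.55, 0.80) * Lz, arm_r = 0.085 * Lx,
    arm_bone_r = 0.028 * Lx, arm_muscle_frac = 0.8,
    head_c = c(xc, yc, 0.93 * Lz), head_r = 0.045 * Lz,
    skull_t = 14,
    neck_r = 45, neck_z = c(0.82, 0.895) * Lz,
    spine_c = c(xc, yc + 0.13 * Ly), spine_r = 0.05 * Lx,
    pelvis_c = c(xc, yc, 0.455 * Lz),
    pelvis_s = c(0.22 * Lx, 0.13 * Ly, 0.04 * Lz),
    heart_c = c(xc - 0.04 * Lx, yc - 0.05 * Ly, 0.72 * Lz),
    heart_s = c(50, 45, 55),
    liver_c = c(xc - 0.16 * Lx, yc - 0.03 * Ly, 0.645 * Lz),
    liver_s = c(90, 68, 78),
    panc_c = c(xc + 0.06 * Lx, yc, 0.625 * Lz),
    panc_s = c(55, 26, 22),
    abdo_c = c(xc, yc - 8), abdo_s = c(0.26 * Lx, 0.22 * Ly),
    abdo_z = c(0.50, 0.64) * Lz
  )
}

# World-coordinate arrays of voxel centres.
coord_arrays <- function(shape, spacing) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  list(
    X = array(rep((0:(nx - 1)) * spacing[1], times = ny * nz), shape),
    Y = array(rep(rep((0:(ny - 1)) * spacing[2], each = nx), times = nz),
              shape),
    Z = array(rep((0:(nz - 1)) * spacing[3], each = nx * ny), shape)
  )
}

#' Reference body phantom
#'
#' Builds the reference anatomy from stacked ellipsoidal/cylindrical
#' primitives: torso, two legs, two arms, head/neck; bone (skull, spine,
#' pelvis, limb bones), liver, pancreas, heart blood pool, an intra-abdominal
#' VAT compartment, and subcutaneous fat shells split at the hip into upper-
#' and lower-body depots. Returns the label volume, the fat-fraction and
#' water volumes at the reference fat-fraction levels, and the region table
#' used to build deformation kernels.
#'
#' @param shape,spacing grid definition as in [phantom_spec()].
#' @return List with `labels`, `fat`, `water` (`imio_volume`s) and
#'   `geometry`.
#' @export
reference_phantom <- function(shape = c(128L, 96L, 250L),
                              spacing = c(4, 4, 8)) {
  g <- phantom_geometry(shape, spacing)
  cc <- coord_arrays(shape, spacing)
  X <- cc$X; Y <- cc$Y; Z <- cc$Z
  lab <- array(.imio_label_codes[["background"]], shape)

  inside_torso <- function(frac) {
    ((X - g$xc) / (frac * g$torso_a))^2 + ((Y - g$yc) / (frac * g$torso_b))^2 <= 1 &
      Z >= g$torso_z[1] & Z <= g$torso_z[2]
  }
  ell <- function(c3, s3) {
    ((X - c3[1]) / s3[1])^2 + ((Y - c3[2]) / s3[2])^2 +
      ((Z - c3[3]) / s3[3])^2 <= 1
  }

  # legs (radius tapers toward the ankle)
  leg_r <- g$leg_r_ankle + (g$leg_r_hip - g$leg_r_ankle) *
    pmin(pmax(Z / g$leg_zmax, 0), 1)
  # legs start one slice above the grid border so warps never sample
  # body tissue outside the volume
  leg_z <- Z <= g$leg_zmax & Z >= 0.02 * g$Lz
  leg_any <- array(FALSE, shape); leg_muscle <- array(FALSE, shape)
  leg_bone <- array(FALSE, shape)
  for (lx in g$leg_x) {
    d2 <- (X - lx)^2 + (Y - g$yc)^2
    in_leg <- d2 <= leg_r^2 & leg_z
    leg_any <- leg_any | in_leg
    leg_muscle <- leg_muscle | (d2 <= (0.75 * leg_r)^2 & leg_z)
    leg_bone <- leg_bone | (d2 <= g$leg_bone_r^2 & leg_z)
  }
  torso <- inside_torso(1)
  torso_core <- inside_torso(g$sat_upper_frac)
  arm_any <- array(FALSE, shape); arm_muscle <- array(FALSE, shape)
  arm_bone <- array(FALSE, shape)
  for (ax in g$arm_x) {
    d2 <- (X - ax)^2 + (Y - g$yc)^2
    in_arm <- d2 <= g$arm_r^2 & Z >= g$arm_z[1] & Z <= g$arm_z[2]
    arm_any <- arm_any | in_arm
    arm_muscle <- arm_muscle |
      (d2 <= (g$arm_muscle_frac * g$arm_r)^2 & Z >= g$arm_z[1] & Z <= g$arm_z[2])
    arm_bone <- arm_bone | (d2 <= g$arm_bone_r^2 & Z >= g$arm_z[1] &
                              Z <= g$arm_z[2])
  }
  head <- ell(g$head_c, rep(g$head_r, 3))
  skull <- head & !ell(g$head_c, rep(g$head_r - g$skull_t, 3))
  neck <- (X - g$xc)^2 + (Y - g$yc)^2 <= g$neck_r^2 &
    Z >= g$neck_z[1] & Z <= g$neck_z[2]
  spine <- (X - g$spine_c[1])^2 + (Y - g$spine_c[2])^2 <= g$spine_r^2 &
    Z >= g$torso_z[1] & Z <= g$torso_z[2]
  pelvis <- ell(g$pelvis_c, g$pelvis_s)
  heart <- ell(g$heart_c, g$heart_s)
  liver <- ell(g$liver_c, g$liver_s)
  panc <- ell(g$panc_c, g$panc_s)
  abdo <- ((X - g$abdo_c[1]) / g$abdo_s[1])^2 +
    ((Y - g$abdo_c[2]) / g$abdo_s[2])^2 <= 1 &
    Z >= g$abdo_z[1] & Z <= g$abdo_z[2]

  body <- leg_any | torso | arm_any | head | neck
  # paint from least to most specific
  k <- .imio_label_codes
  lab[body] <- k[["other_lean"]]
  lab[leg_any] <- k[["sat_lower"]]
  lab[leg_muscle] <- k[["leg_muscle"]]
  lab[torso & !torso_core] <- k[["sat_upper"]]
  lab[arm_any & !arm_muscle] <- k[["sat_upper"]]
  lab[arm_muscle] <- k[["arm_muscle"]]
  lab[abdo & torso_core] <- k[["vat"]]
  lab[liver & torso] <- k[["liver"]]
  lab[panc & torso] <- k[["pancreas"]]
  lab[heart & torso] <- k[["heart_blood"]]
  lab[spine | pelvis | leg_bone | arm_bone | skull] <- k[["bone"]]

  ffv <- .imio_default_ff[match(as.integer(lab), .imio_label_codes)]
  fat <- array(as.numeric(ffv), shape)
  water <- array(ifelse(lab > 0, 1 - fat, 0), shape)
  list(labels = imio_volume(lab, spacing),
       fat = imio_volume(fat, spacing),
       water = imio_volume(water, spacing),
       geometry = g)
}

# Compact-support radial scaling kernels: per scalable region, one or more
# ellipsoidal-support kernels (centre, support radii in mm). Supports are
# sized so the labelled region sits inside the kernel plateau (exact local
# scaling, Jacobian s^3 there) while the compensating compression annulus
# falls outside the body or in unanalysed lean tissue; perimeter bumps are
# used for the subcutaneous shells so depot-core voxels respond only to
# their own region's scale.
phantom_kernels <- function(g) {
  list(
    leg_muscle = list(
      list(c = c(g$leg_x[1], g$yc, 0.32 * g$Lz), r = c(105, 105, 310)),
      list(c = c(g$leg_x[2], g$yc, 0.32 * g$Lz), r = c(105, 105, 310)),
      list(c = c(g$leg_x[1], g$yc, 0.10 * g$Lz), r = c(95, 95, 310)),
      list(c = c(g$leg_x[2], g$yc, 0.10 * g$Lz), r = c(95, 95, 310))),
    arm_muscle = list(
      list(c = c(g$arm_x[1], g$yc, mean(g$arm_z)), r = c(70, 70, 330)),
      list(c = c(g$arm_x[2], g$yc, mean(g$arm_z)), r = c(70, 70, 330))),
    vat = list(
      list(c = c(g$abdo_c[1], g$abdo_c[2], mean(g$abdo_z)),
           r = c(370, 250, 280))),
    sat_upper = list(
      list(c = c(g$xc - 0.317 * g$Lx, g$yc, 0.635 * g$Lz), r = c(70, 140, 430)),
      list(c = c(g$xc + 0.317 * g$Lx, g$yc, 0.635 * g$Lz), r = c(70, 140, 430)),
      list(c = c(g$xc, g$yc - 0.28 * g$Ly, 0.635 * g$Lz), r = c(150, 55, 430)),
      list(c = c(g$xc, g$yc + 0.28 * g$Ly, 0.635 * g$Lz), r = c(150, 55, 430))),
    sat_lower = list(
      list(c = c(g$leg_x[1] - 65, g$yc, 0.24 * g$Lz), r = c(60, 95, 470)),
      list(c = c(g$leg_x[2] + 65, g$yc, 0.24 * g$Lz), r = c(60, 95, 470))),
    liver = list(list(c = g$liver_c, r = c(165, 125, 145))),
    heart_blood = list(list(c = g$heart_c, r = c(91, 82, 100)))
  )
}

# Compactly supported radial bump: 1 on a central plateau (q <= plateau),
# Wendland C2 decay to 0 at q = 1. The plateau makes the mapping an exact
# local scaling (Jacobian s^3) at the region core.
wendland <- function(q, plateau = 0.55) {
  qq <- pmax((q - plateau) / (1 - plateau), 0)
  ifelse(qq < 1, (1 - qq)^4 * (4 * qq + 1), 0)
}

#' Kernel-plateau core mask of a scalable region
#'
#' Voxels of a region that lie inside the plateau of (one of) its scaling
#' kernels, where the ground-truth Jacobian equals the regional scale
#' factor exactly by construction. Used to validate Jacobian recovery away
#' from the kernel transition shells.
#'
#' @param region one of the scalable region names.
#' @param shape,spacing grid definition.
#' @param plateau plateau fraction of the kernel support (default 0.55,
#'   matching the generator).
#' @return Logical array on the grid.
#' @export
region_core_mask <- function(region, shape = c(128L, 96L, 250L),
                             spacing = c(4, 4, 8), plateau = 0.55) {
  if (!region %in% .imio_scalable) stop("not a scalable region: ", region)
  ref <- reference_phantom(shape, spacing)
  g <- ref$geometry
  kern <- phantom_kernels(g)[[region]]
  cc <- coord_arrays(shape, spacing)
  core <- array(FALSE, shape)
  for (kk in kern) {
    q <- sqrt(((cc$X - kk$c[1]) / kk$r[1])^2 +
                ((cc$Y - kk$c[2]) / kk$r[2])^2 +
                ((cc$Z - kk$c[3]) / kk$r[3])^2)
    core <- core | q <= plateau
  }
  core & ref$labels$data == .imio_label_codes[[region]]
}

# Analytic ground-truth displacement at arbitrary mm points.
phantom_field_fun <- function(spec, g) {
  kern <- phantom_kernels(g)
  function(px, py, pz) {
    ux <- numeric(length(px)); uy <- numeric(length(px))
    uz <- numeric(length(px))
    for (region in names(kern)) {
      s <- spec$scales[[region]]
      if (abs(s - 1) < 1e-12) next
      for (kk in kern[[region]]) {
        dx <- px - kk$c[1]; dy <- py - kk$c[2]; dz <- pz - kk$c[3]
        q <- sqrt((dx / kk$r[1])^2 + (dy / kk$r[2])^2 + (dz / kk$r[3])^2)
        w <- (s - 1) * wendland(q)
        ux <- ux + w * dx; uy <- uy + w * dy; uz <- uz + w * dz
      }
    }
    cbind(ux, uy, uz)
  }
}

#' Generate a subject phantom with ground-truth deformation
#'
#' Applies the spec's per-region scalings as a sum of compactly supported
#' radial scaling kernels, giving a globally smooth, invertible
#' reference-to-subject displacement field (the ground truth). The subject
#' label volume is the reference anatomy carried through the (numerically
#' inverted) field; fat fractions are the spec's region levels plus clipped
#' Gaussian noise, and the water signal is `1 - fat fraction` inside the
#' body.
#'
#' @param spec an `imio_phantom_spec`.
#' @param seed integer seed for the fat-fraction noise.
#' @return An `imio_phantom`: list with `fat`, `water`, `labels`
#'   (`imio_volume`s on the subject grid), `gt_field` (reference-to-subject
#'   `imio_field` on the reference grid) and `spec`.
#' @export
generate_phantom <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "imio_phantom_spec"))
  if (any(spec$scales < 0.5 | spec$scales > 2))
    stop("region scale factors must lie in [0.5, 2]")
  ref <- reference_phantom(spec$shape, spec$spacing)
  g <- ref$geometry
  ufun <- phantom_field_fun(spec, g)
  cc <- coord_arrays(spec$shape, spec$spacing)
  px <- as.numeric(cc$X); py <- as.numeric(cc$Y); pz <- as.numeric(cc$Z)

  # ground truth on the reference grid
  U <- ufun(px, py, pz)
  gt <- imio_field(array(U, c(spec$shape, 3)), spec$spacing)

  # subject labels: invert the analytic field by fixed-point iteration
  vx <- numeric(length(px)); vy <- vx; vz <- vx
  for (it in 1:8) {
    Ui <- ufun(px + vx, py + vy, pz + vz)
    vx <- -Ui[, 1]; vy <- -Ui[, 2]; vz <- -Ui[, 3]
  }
  vfield <- array(c(vx, vy, vz), c(spec$shape, 3))
  sub_lab <- warp_volume_cpp(as.numeric(ref$labels$data),
                             as.integer(spec$shape), as.numeric(vfield),
                             spec$spacing, 1L, 0)
  sub_lab <- array(as.integer(sub_lab), spec$shape)

  # subject intensities: the reference-geometry fat/water fields at the
  # subject's per-region levels, carried through the inverse map with
  # trilinear interpolation so tissue boundaries are anti-aliased (partial
  # volume) and sub-voxel boundary positions are observable
  ffv_ref <- array(as.numeric(
    spec$ff[match(as.integer(ref$labels$data), .imio_label_codes)]),
    spec$shape)
  water_ref <- array(0, spec$shape)
  water_ref[ref$labels$data > 0] <- 1 - ffv_ref[ref$labels$data > 0]
  fat <- array(warp_volume_cpp(as.numeric(ffv_ref), as.integer(spec$shape),
                               as.numeric(vfield), spec$spacing, 0L, 0),
               spec$shape)
  water <- array(warp_volume_cpp(as.numeric(water_ref),
                                 as.integer(spec$shape),
                                 as.numeric(vfield), spec$spacing, 0L, 0),
                 spec$shape)
  # depot construction invariant: adipose-labelled voxels keep FF >= 0.5
  # even where partial-volume mixing at a boundary would dilute them
  k <- .imio_label_codes
  depot <- sub_lab %in% k[c("vat", "sat_upper", "sat_lower")]
  fat[depot] <- pmax(fat[depot], 0.5)
  lab_pos <- sub_lab > 0
  noisy <- with_seed(seed, {
    if (spec$noise_sd > 0) {
      fat[lab_pos] <- fat[lab_pos] +
        rnorm(sum(lab_pos), 0, spec$noise_sd)
      water[lab_pos] <- water[lab_pos] +
        rnorm(sum(lab_pos), 0, spec$noise_sd)
    }
    list(fat = pmin(pmax(fat, 0), 1), water = pmin(pmax(water, 0), 1))
  })
  fat <- noisy$fat
  water <- noisy$water

  structure(list(fat = imio_volume(fat, spec$spacing),
                 water = imio_volume(water, spec$spacing),
                 labels = imio_volume(sub_lab, spec$spacing),
                 gt_field = gt, spec = spec),
            class = "imio_phantom")
}

#' @export
print.imio_phantom <- function(x, ...) {
  cat("Body phantom", paste(x$spec$shape, collapse = "x"), "voxels at",
      paste(x$spec$spacing, collapse = "x"), "mm\n")
  sc <- x$spec$scales[abs(x$spec$scales - 1) > 1e-9]
  if (length(sc))
    cat("  scaled regions:",
        paste(sprintf("%s=%.2f", names(sc), sc), collapse = ", "), "\n")
  invisible(x)
}

#' Link phantom specs to a cohort
#'
#' Maps each subject's body-composition variables to per-region phantom
#' scale factors: the regional volume scale is the cube root of the
#' subject's value relative to the sex-stratum median (so the median subject
#' of each sex gets scale 1 and regional volume grows proportionally with
#' the cohort variable). VAT follows cohort VAT, upper SAT follows trunk+arm
#' fat mass, lower SAT follows leg fat mass, leg muscle follows leg lean
#' mass, arm muscle follows arm lean mass, and the heart blood pool follows
#' total lean mass. Liver and pancreas fat-fraction levels equal the
#' cohort's liver/pancreas fat percentages (stratum median where the liver
#' scan is flagged missing).
#'
#' @param cohort an `imio_cohort`.
#' @param seed kept for interface symmetry; the mapping is deterministic.
#' @param shape,spacing,noise_sd forwarded to [phantom_spec()].
#' @return List of `imio_phantom_spec`, one per cohort row, named by
#'   subject id.
#' @export
link_phantom_specs <- function(cohort, seed = 1,
                               shape = c(128L, 96L, 250L),
                               spacing = c(4, 4, 8), noise_sd = 0.02) {
  if (!nrow(cohort)) stop("cohort is empty")
  need <- c("id", "sex", "vat", "fat_trunk", "fat_arm", "fat_leg",
            "lean_leg", "lean_arm", "lean_total", "liver_fat",
            "pancreas_fat", "liver_scan_missing")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  med <- function(v, sx) median(v[cohort$sex == sx], na.rm = TRUE)
  clip_scale <- function(s) pmin(pmax(s, 0.5), 2)
  specs <- lapply(seq_len(nrow(cohort)), function(i) {
    sx <- cohort$sex[i]
    rel <- function(col) {
      v <- cohort[[col]][i]
      if (is.na(v)) v <- med(cohort[[col]], sx)
      (v / med(cohort[[col]], sx))^(1 / 3)
    }
    lf <- cohort$liver_fat[i]
    if (is.na(lf)) lf <- med(cohort$liver_fat, sx)
    pf <- cohort$pancreas_fat[i]
    if (is.na(pf)) pf <- med(cohort$pancreas_fat, sx)
    trunk_arm <- cohort$fat_trunk[i] + cohort$fat_arm[i]
    med_ta <- median((cohort$fat_trunk + cohort$fat_arm)[cohort$sex == sx],
                     na.rm = TRUE)
    phantom_spec(
      scales = clip_scale(c(
        vat = rel("vat"),
        sat_upper = (trunk_arm / med_ta)^(1 / 3),
        sat_lower = rel("fat_leg"),
        leg_muscle = rel("lean_leg"),
        arm_muscle = rel("lean_arm"),
        heart_blood = rel("lean_total"),
        liver = 1
      )),
      ff = c(liver = min(lf / 100, 1), pancreas = min(pf / 100, 1)),
      shape = shape, spacing = spacing, noise_sd = noise_sd
    )
  })
  names(specs) <- cohort$id
  specs
}
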