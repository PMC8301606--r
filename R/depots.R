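#' Depot atlas from the reference anatomy
#'
#' Reference-space VAT and SAT depot masks (SAT = upper + lower shells) and
#' liver/pancreas VOI masks, taken from the reference phantom labels.
#'
#' @param ref output of [reference_phantom()] (or any list with a `labels`
#'   `imio_volume`).
#' @return An `imio_atlas`: list of logical arrays `vat`, `sat`, `liver`,
#'   `pancreas` plus `spacing`.
#' @export
reference_atlas <- function(ref) {
  lab <- ref$labels$data
  k <- .imio_label_codes
  structure(list(
    vat = lab == k[["vat"]],
    sat = lab == k[["sat_upper"]] | lab == k[["sat_lower"]],
    liver = lab == k[["liver"]],
    pancreas = lab == k[["pancreas"]],
    spacing = ref$labels$spacing
  ), class = "imio_atlas")
}

#' Atlas-propagated depot segmentation with fat-content thresholding
#'
#' Carries the reference-space depot masks into subject space through the
#' registration field (nearest-neighbour label transport via the inverted
#' field, so the subject-space region is solid), then excludes voxels with
#' fat content below 50% (fat fraction >= 0.5 retained, boundary
#' inclusive). Volumes are retained-voxel counts times the voxel volume, in
#' litres.
#'
#' @param atlas an `imio_atlas` on the reference grid.
#' @param field reference-to-subject `imio_field` (identity if `NULL`).
#' @param fat subject-space fat-fraction `imio_volume`.
#' @param ff_threshold inclusive fat-fraction retention threshold
#'   (default 0.5).
#' @return An `imio_depots`: `vat_l`, `sat_l` (litres) and the retained
#'   subject-space masks `vat_mask`, `sat_mask`.
#' @export
segment_depots <- function(atlas, field = NULL, fat,
                           ff_threshold = 0.5) {
  stopifnot(inherits(atlas, "imio_atlas"))
  d <- dim(fat$data)
  if (!identical(dim(atlas$vat), d))
    stop("atlas and fat volume are not on the same grid")
  if (is.null(field)) field <- zero_field(d, fat$spacing)
  check_same_grid(fat, field, "fat volume and field")
  inv <- invert_field(field)
  carry <- function(mask) {
    m <- warp_volume_cpp(as.numeric(mask * 1), as.integer(d),
                         as.numeric(inv$u), fat$spacing, 1L, 0)
    array(m > 0.5, d)
  }
  vat_s <- carry(atlas$vat) & fat$data >= ff_threshold
  sat_s <- carry(atlas$sat) & fat$data >= ff_threshold
  voxvol_l <- prod(fat$spacing) / 1e6
  structure(list(vat_l = sum(vat_s) * voxvol_l,
                 sat_l = sum(sat_s) * voxvol_l,
                 vat_mask = vat_s, sat_mask = sat_s,
                 spacing = fat$spacing),
            class = "imio_depots")
}

#' @export
print.imio_depots <- function(x, ...) {
  cat(sprintf("Depot volumes: VAT %.2f L, SAT %.2f L\n", x$vat_l, x$sat_l))
  invisible(x)
}

# 6-connected single-voxel erosion of a logical mask.
erode1 <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len)
    dst <- src
    if (by > 0) {
      dst[[ax]] <- seq_len(d[ax] - by) + by
      src[[ax]] <- seq_len(d[ax] - by)
    } else {
      dst[[ax]] <- seq_len(d[ax] + by)
      src[[ax]] <- seq_len(d[ax] + by) - by
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  out <- mask
  for (ax in 1:3) for (by in c(-1, 1))
    out <- out & shift(mask, ax, by)
  out
}

#' Median fat content of a volume of interest
#'
#' The VOI is eroded by one voxel to avoid tissue borders (limiting partial
#' volume effects), then the median fat fraction over the remaining voxels
#' is returned as a percentage. Even-sized samples use the
#' average-of-the-two-middle-values convention.
#'
#' @param fat fat-fraction `imio_volume`.
#' @param voi logical array on the same grid.
#' @return Median fat content in percent.
#' @export
voi_fat_content <- function(fat, voi) {
  if (!identical(dim(fat$data), dim(voi)))
    stop("fat volume and VOI are not on the same grid")
  if (!any(voi)) stop("empty VOI")
  core <- erode1(voi)
  if (!any(core)) stop("VOI empty after border erosion")
  100 * median(fat$data[core])
}

#' Regional fat and lean mass summaries from labels
#'
#' Planar-absorptiometry-style regional summary computed directly from the
#' phantom labels: per region (total body, trunk, legs, arms), fat mass =
#' sum of fat fraction x voxel volume x 0.92 kg/L and lean mass = sum of
#' (1 - fat fraction) x voxel volume x 1.06 kg/L over soft-tissue voxels
#' (standard adipose/lean tissue densities).
#'
#' @param labels integer label `imio_volume`.
#' @param fat fat-fraction `imio_volume` on the same grid.
#' @return An `imio_region_summary` data frame with `region`, `fat_kg`,
#'   `lean_kg`.
#' @export
region_summaries <- function(labels, fat) {
  check_same_grid(labels, fat)
  k <- .imio_label_codes
  known <- unname(k)
  seen <- unique(as.integer(labels$data))
  unknown <- setdiff(seen, known)
  if (length(unknown))
    warning("unknown label codes skipped: ", paste(unknown, collapse = ", "))
  soft <- !(labels$data %in% c(k[["background"]], k[["bone"]])) &
    !(labels$data %in% unknown)
  regions <- list(
    total = soft,
    trunk = soft & (labels$data %in% k[c("vat", "sat_upper", "liver",
                                         "pancreas", "heart_blood")]),
    leg = soft & (labels$data %in% k[c("leg_muscle", "sat_lower")]),
    arm = soft & (labels$data %in% k[["arm_muscle"]])
  )
  voxvol_l <- prod(fat$spacing) / 1e6
  rows <- lapply(names(regions), function(nm) {
    m <- regions[[nm]]
    ffs <- fat$data[m]
    data.frame(region = nm,
               fat_kg = sum(ffs) * voxvol_l * 0.92,
               lean_kg = sum(1 - ffs) * voxvol_l * 1.06)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("imio_region_summary", "data.frame")
  out
}
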