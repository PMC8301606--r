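test_that("tissue segmentation follows the label and threshold rules", {
  ph <- test_ref_phantom()
  m <- segment_tissues(ph$fat, ph$water, ph$labels)
  expect_identical(m$bone, ph$labels$data == imio_labels()[["bone"]])
  expect_true(all(!(m$bone & m$lean)) && all(!(m$bone & m$fat)) &&
                all(!(m$lean & m$fat)))
  expect_true(all((m$bone | m$lean | m$fat) <= m$body))

  z <- imio_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  mz <- segment_tissues(z, z)
  expect_identical(sum(mz$bone) + sum(mz$lean) + sum(mz$fat), 0L)

  # threshold boundary: fat fraction 0.49 -> lean, 0.51 -> fat
  fat <- array(0.49, c(3, 3, 3)); fat[2, 2, 2] <- 0.51
  water <- array(0.5, c(3, 3, 3))
  mm <- segment_tissues(imio_volume(fat, c(1, 1, 1)),
                        imio_volume(water, c(1, 1, 1)))
  expect_true(mm$fat[2, 2, 2])
  expect_true(all(mm$lean[fat == 0.49]))

  bad <- imio_volume(array(0, c(5, 4, 4)), c(1, 1, 1))
  expect_error(segment_tissues(bad, z), "same grid")
})

test_that("articulated bone registration recovers identity, shift and scale", {
  ph <- test_ref_phantom()
  m <- segment_tissues(ph$fat, ph$water, ph$labels)
  expect_error(register_bones(m, segment_tissues(
    imio_volume(array(0, dim(ph$fat$data)), ph$fat$spacing),
    imio_volume(array(0, dim(ph$fat$data)), ph$fat$spacing))), "empty bone")

  idreg <- register_bones(m, m, refine = FALSE)
  for (a in idreg$affines) {
    expect_equal(a$scale, c(1, 1, 1), tolerance = 1e-6)
    expect_equal(a$subj_center - a$ref_center, c(0, 0, 0),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }

  # whole-body shift by one z voxel: every affine's translation matches
  d <- dim(ph$fat$data)
  shift1 <- function(arr) {
    out <- array(0, d)
    out[, , 2:d[3]] <- arr[, , 1:(d[3] - 1)]
    out
  }
  subj <- list(fat = imio_volume(shift1(ph$fat$data), ph$fat$spacing),
               water = imio_volume(shift1(ph$water$data), ph$fat$spacing),
               labels = imio_volume(shift1(ph$labels$data), ph$fat$spacing))
  ms <- segment_tissues(subj$fat, subj$water, subj$labels)
  sreg <- register_bones(m, ms, refine = FALSE)
  dz <- ph$fat$spacing[3]
  for (s in intersect(names(sreg$affines), c("spine", "leg_left",
                                             "leg_right", "pelvis"))) {
    a <- sreg$affines[[s]]
    expect_equal(unname(a$subj_center - a$ref_center), c(0, 0, dz),
                 tolerance = 0.35 * dz)
  }

  # subject with both leg bones isotropically 1.1x larger (drawn from the
  # analytic geometry, so the masks genuinely express the scale): the leg
  # affine determinant approaches 1.1^3, other segments stay at identity
  g <- phantom_geometry(test_shape, test_spacing)
  cc <- coord_arrays(test_shape, test_spacing)
  bone2 <- m$bone
  zc <- 0.23 * g$Lz  # mid-leg
  in_legs_z <- cc$Z >= 0.02 * g$Lz & cc$Z <= g$leg_zmax
  for (lx in g$leg_x) {
    d2 <- (cc$X - lx)^2 + (cc$Y - g$yc)^2
    old_bone <- d2 <= g$leg_bone_r^2 & in_legs_z
    bone2[old_bone] <- FALSE
    new_bone <- d2 <= (1.1 * g$leg_bone_r)^2 &
      abs(cc$Z - zc) <= 1.1 * (g$leg_zmax / 2 - 0.02 * g$Lz) &
      cc$Z >= 0 & cc$Z <= g$leg_zmax
    bone2[new_bone] <- TRUE
  }
  m2 <- m
  m2$bone <- bone2
  reg2 <- register_bones(m, m2, refine = FALSE)
  expect_equal(prod(reg2$affines$leg_left$scale), 1.1^3, tolerance = 0.12)
  expect_equal(prod(reg2$affines$leg_right$scale), 1.1^3, tolerance = 0.12)
  expect_equal(prod(reg2$affines$skull$scale), 1, tolerance = 0.05)
})

test_that("constrained demons: identity pair, freeze contract, errors", {
  ph <- test_ref_phantom()
  m <- segment_tissues(ph$fat, ph$water, ph$labels)
  d <- dim(ph$water$data)
  zf <- zero_field(d, ph$water$spacing)
  f <- register_elastic(ph$water, ph$water, "water", constraint = zf,
                        masks = m, iters = 15)
  mag <- sqrt(f$u[, , , 1]^2 + f$u[, , , 2]^2 + f$u[, , , 3]^2)
  expect_lt(max(mag), 0.5 * min(ph$water$spacing))

  expect_error(register_elastic(ph$water, ph$water, "water", sigma = -1),
               "positive")

  # frozen voxels equal the constraint bit-exactly
  subj <- generate_phantom(phantom_spec(scales = c(vat = 1.25),
                                        shape = test_shape,
                                        spacing = test_spacing), seed = 3)
  bone <- register_bones(m, segment_tissues(subj$fat, subj$water,
                                            subj$labels))
  fw <- register_elastic(ph$water, subj$water, "water",
                         constraint = bone$field, masks = m, iters = 15)
  for (c in 1:3) {
    uc <- fw$u[, , , c]; bc <- bone$field$u[, , , c]
    expect_identical(uc[m$bone], bc[m$bone])
  }
})

test_that("Jacobian map matches analytic fields", {
  d <- c(12L, 12L, 12L)
  sp <- c(2, 2, 2)
  expect_equal(range(jacobian_map(zero_field(d, sp))$data), c(1, 1))
  # constant translation
  tr <- array(0, c(d, 3)); tr[, , , 3] <- 5
  expect_equal(range(jacobian_map(imio_field(tr, sp))$data), c(1, 1))
  # global isotropic expansion u = 0.1 x -> det = 1.331 in the interior
  cc <- coord_arrays(d, sp)
  u <- array(0, c(d, 3))
  u[, , , 1] <- 0.1 * cc$X; u[, , , 2] <- 0.1 * cc$Y; u[, , , 3] <- 0.1 * cc$Z
  J <- jacobian_map(imio_field(u, sp))$data
  expect_equal(unname(J[2:11, 2:11, 2:11]),
               array(1.1^3, c(10, 10, 10)), tolerance = 1e-9)
})

test_that("pull_to_reference interpolates and recovers known translations", {
  d <- c(10L, 10L, 10L); sp <- c(2, 2, 2)
  vol <- imio_volume(array(rnorm(prod(d)), d), sp)
  zf <- zero_field(d, sp)
  expect_equal(pull_to_reference(vol, zf)$data, vol$data, tolerance = 1e-12)

  cvol <- imio_volume(array(3.5, d), sp)
  rf <- imio_field(array(runif(prod(d) * 3, -2, 2), c(d, 3)), sp)
  inside <- pull_to_reference(cvol, rf)$data[3:8, 3:8, 3:8]
  expect_equal(unname(inside), array(3.5, c(6, 6, 6)), tolerance = 1e-12)

  # delta blob shifted by one voxel is recovered at the reference location
  blob <- array(0, d); blob[6, 6, 6] <- 1
  shifted <- array(0, d); shifted[6, 6, 7] <- 1
  tf <- array(0, c(d, 3)); tf[, , , 3] <- sp[3]
  rec <- pull_to_reference(imio_volume(shifted, sp), imio_field(tf, sp))
  expect_equal(rec$data[6, 6, 6], 1)
  expect_equal(sum(rec$data), 1)
})

test_that("full pipeline recovers a known deformation to sub-voxel error", {
  ref <- test_ref_phantom()
  subj <- generate_phantom(phantom_spec(
    scales = c(vat = 1.25, leg_muscle = 1.08, sat_upper = 0.9),
    shape = test_shape, spacing = test_spacing), seed = 5)
  reg <- suppressWarnings(register_subject(ref, subj, iters = 40))
  gt <- subj$gt_field
  body <- ref$labels$data > 0
  epe <- sqrt((reg$field$u[, , , 1] - gt$u[, , , 1])^2 +
                (reg$field$u[, , , 2] - gt$u[, , , 2])^2 +
                (reg$field$u[, , , 3] - gt$u[, , , 3])^2)
  expect_lt(mean(epe[body]), max(test_spacing))
  # volume consistency: integrated Jacobian over the body approximates the
  # subject body volume
  est <- sum(reg$jacobian$data[body])
  subj_body <- sum(subj$labels$data > 0)
  expect_equal(est / subj_body, 1, tolerance = 0.05)
})

test_that("fields and volumes round-trip through NIfTI", {
  ph <- generate_phantom(phantom_spec(scales = c(vat = 1.2),
                                      shape = tiny_shape,
                                      spacing = tiny_spacing), seed = 1)
  vp <- withr::local_tempfile(fileext = ".nii.gz")
  fp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$fat, vp)
  back <- read_volume(vp)
  expect_equal(back$data, ph$fat$data, tolerance = 1e-6)
  expect_equal(back$spacing, ph$fat$spacing, tolerance = 1e-5)
  write_field(ph$gt_field, fp)
  fback <- read_field(fp)
  expect_equal(fback$u, ph$gt_field$u, tolerance = 1e-4)
})
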