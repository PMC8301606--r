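test_that("default calibration reproduces the published marginals and is PSD", {
  cal <- default_calibration()
  expect_equal(cal$female$mean[["imt"]], 0.62)
  expect_equal(cal$female$sd[["imt"]], 0.11)
  expect_equal(cal$male$mean[["vat"]], 4.4)
  expect_equal(cal$female$mean[["imgsm"]], 68.1)
  expect_true(all(cal$female$sd > 0))
  for (sx in c("female", "male")) {
    R <- cal[[sx]]$R
    expect_true(isSymmetric(unname(R), tol = 1e-8))
    expect_equal(unname(diag(R)), rep(1, nrow(R)))
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
  # the weighted PSD repair preserves the published outcome rows
  expect_equal(cal$female$R["imgsm", "vat"], -0.41, tolerance = 0.01)
  expect_equal(cal$female$R["imgsm", "lean_total"], -0.75, tolerance = 0.01)
  expect_equal(cal$male$R["imt", "lean_total"], 0.32, tolerance = 0.01)
})

test_that("nearest-PSD repair fixes an indefinite matrix and respects weights", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9   # indefinite
  fixed <- nearest_psd_correlation(R)
  ev <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_equal(diag(fixed), rep(1, 3))
  # independent cross-check against the reference implementation
  ref <- as.matrix(Matrix::nearPD(R, corr = TRUE, keepDiag = TRUE)$mat)
  expect_equal(unname(fixed), unname(ref), tolerance = 1e-4)
  # weighting variable 1 heavily keeps its entries closer to the target
  fw <- nearest_psd_correlation(R, weights = c(50, 1, 1))
  expect_lt(abs(fw[1, 2] - 0.9) + abs(fw[1, 3] - 0.9),
            abs(fixed[1, 2] - 0.9) + abs(fixed[1, 3] - 0.9))
})

test_that("cohort generation honours contracts and derived columns", {
  expect_error(generate_cohort(-1, 10), "non-negative")
  empty <- generate_cohort(0, 0, default_calibration(), seed = 1)
  expect_s3_class(empty, "imio_cohort")
  expect_identical(nrow(empty), 0L)

  coh <- small_cohort()
  expect_identical(nrow(coh), 80L)
  # bit-identical reproduction under the same seed
  expect_identical(coh, generate_cohort(40, 40, default_calibration(),
                                        seed = 7))
  expect_false(identical(coh, generate_cohort(40, 40, default_calibration(),
                                              seed = 8)))
  # deterministic derived columns
  expect_equal(coh$bmi, coh$weight / (coh$height / 100)^2, tolerance = 1e-12)
  expect_equal(coh$whr, coh$waist / coh$hip, tolerance = 1e-12)
  # physical ranges
  pos <- c("imt", "height", "weight", "waist", "hip", "fat_total",
           "lean_total", "vat", "sat")
  for (nm in pos) expect_true(all(coh[[nm]] > 0), label = nm)
  expect_true(all(coh$imgsm >= 0 & coh$imgsm <= 256))
  expect_true(all(coh$smoking %in% 0:1))
  # liver-scan missingness matches the per-sex calibration counts
  full <- generate_cohort(165, 156, default_calibration(), seed = 1)
  expect_identical(sum(full$liver_scan_missing[full$sex == "female"]), 27L)
  expect_identical(sum(full$liver_scan_missing[full$sex == "male"]), 35L)
  expect_true(all(is.na(full$liver_fat[full$liver_scan_missing])))
})

test_that("large-sample cohort converges to the calibration", {
  cal <- default_calibration()
  big <- generate_cohort(10000, 0, cal, seed = 1)
  # marginal means within 3 standard errors at n = 10^4
  for (nm in c("imt", "imgsm", "sbp", "lean_total")) {
    se <- cal$female$sd[[nm]] / sqrt(10000)
    expect_lt(abs(mean(big[[nm]]) - cal$female$mean[[nm]]), 3 * se,
              label = nm)
  }
  # log-normal variables are calibrated on the arithmetic scale
  expect_equal(mean(big$vat), cal$female$mean[["vat"]], tolerance = 0.05)
  # Monte-Carlo check of the copula against the spec's own matrix
  r <- cor(big$imgsm, log(big$vat))
  expect_lt(abs(r - cal$female$R["imgsm", "vat"]), 0.03)
  # binary prevalence within 3 binomial SE
  p <- cal$female$smoking_prev
  expect_lt(abs(mean(big$smoking) - p), 3 * sqrt(p * (1 - p) / 1e4))
})

test_that("cohort CSV round-trips", {
  coh <- small_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12)
})

test_that("phantom specs link monotonically to cohort variables", {
  coh <- small_cohort()
  expect_error(link_phantom_specs(coh[, 1:4]), "lacks columns")
  specs <- link_phantom_specs(coh, shape = tiny_shape,
                              spacing = tiny_spacing)
  expect_identical(names(specs), coh$id)
  vat_scale <- vapply(specs, function(s) s$scales[["vat"]], 0)
  leg_scale <- vapply(specs, function(s) s$scales[["leg_muscle"]], 0)
  for (sx in c("female", "male")) {
    i <- coh$sex == sx
    # anchoring: the stratum-median subject has scale 1
    expect_equal(unname(sort(vat_scale[i])[sum(i) / 2 + 0.5]), 1,
                 tolerance = 0.05)
    # monotone by construction: rank correlation exactly 1
    expect_equal(cor(vat_scale[i], coh$vat[i], method = "spearman"), 1)
    expect_equal(cor(leg_scale[i], coh$lean_leg[i], method = "spearman"), 1)
  }
  # liver fat level equals the cohort value (scanned subjects)
  j <- which(!coh$liver_scan_missing)[1]
  expect_equal(specs[[j]]$ff[["liver"]], coh$liver_fat[j] / 100)
})

test_that("phantom generation: identity, analytic Jacobian, depots, determinism", {
  sp0 <- phantom_spec(shape = tiny_shape, spacing = tiny_spacing,
                      noise_sd = 0)
  ph0 <- generate_phantom(sp0, seed = 1)
  expect_equal(max(abs(ph0$gt_field$u)), 0)
  expect_equal(range(jacobian_map(ph0$gt_field)$data), c(1, 1))
  # VAT voxels keep fat fraction >= 0.5 before noise
  expect_true(all(ph0$fat$data[ph0$labels$data ==
                                 imio_labels()[["vat"]]] >= 0.5))
  # body is one connected component
  lab <- label_components26_cpp(as.logical(ph0$labels$data > 0),
                                as.integer(dim(ph0$labels$data)))
  expect_identical(attr(lab, "n_components"), 1L)

  # isotropic 1.1 scaling of the leg muscle: finite-difference Jacobian of
  # the emitted field equals the analytic 1.1^3 at the kernel core
  sp1 <- phantom_spec(scales = c(leg_muscle = 1.1), shape = test_shape,
                      spacing = test_spacing, noise_sd = 0)
  ph1 <- generate_phantom(sp1, seed = 1)
  g <- phantom_geometry(test_shape, test_spacing)
  ij <- round(c(g$leg_x[1] / test_spacing[1], g$yc / test_spacing[2],
                0.32 * g$Lz / test_spacing[3])) + 1
  J <- jacobian_map(ph1$gt_field)$data
  expect_equal(J[ij[1], ij[2], ij[3]], 1.1^3, tolerance = 1e-3)
  # invertible ground truth
  expect_gt(min(J), 0)

  expect_error(phantom_spec(scales = c(vat = 2.5)), "0.5")
  # determinism
  sp2 <- phantom_spec(scales = c(vat = 1.2), shape = tiny_shape,
                      spacing = tiny_spacing)
  expect_identical(generate_phantom(sp2, seed = 3)$fat$data,
                   generate_phantom(sp2, seed = 3)$fat$data)
})

test_that("linked phantom population has invertible ground truth", {
  coh <- small_cohort()
  specs <- link_phantom_specs(coh[seq(1, 80, by = 16), ],
                              shape = tiny_shape, spacing = tiny_spacing)
  for (s in specs) {
    ph <- generate_phantom(s, seed = 11)
    expect_gt(min(jacobian_map(ph$gt_field)$data), 0)
  }
})

test_that("calibration JSON round-trips", {
  cal <- default_calibration()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$female$mean, cal$female$mean, tolerance = 1e-12)
  expect_equal(unname(back$male$R), unname(cal$male$R), tolerance = 1e-12)
})
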