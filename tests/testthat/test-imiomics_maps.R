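# library-free Spearman oracle: average ranks + product-moment formula
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

series_from_matrix <- function(M, spacing = c(1, 1, 1)) {
  # M: subjects x voxels; wrap as a V x 1 x 1 grid series
  structure(list(X = M, dim = c(ncol(M), 1L, 1L), spacing = spacing,
                 channel = "volume", ids = as.character(seq_len(nrow(M)))),
            class = "imio_series")
}

test_that("voxel series stack in cohort order and validate ids", {
  coh <- small_cohort()[1:3, ]
  vol <- imio_volume(array(1:27 / 27, c(3, 3, 3)), c(1, 1, 1))
  maps <- setNames(list(vol, vol, vol), coh$id)
  s <- build_voxel_series(maps, coh, "volume")
  expect_identical(dim(s$X), c(3L, 27L))
  expect_equal(apply(s$X, 2, var), rep(0, 27))
  expect_error(build_voxel_series(setNames(maps, rev(coh$id)), coh),
               "match cohort ids")
})

test_that("spearman_map matches hand computation and the rank oracle", {
  # worked example: d^2 sum = 4 -> rho = 1 - 6*4/(5*24) = 0.8
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  s <- series_from_matrix(cbind(x, x))
  m <- spearman_map(s, y)
  expect_equal(m$coef[1, 1, 1], 0.8, tolerance = 1e-12)

  # y equal to the voxel's own series
  m2 <- spearman_map(series_from_matrix(cbind(x)), x)
  expect_equal(m2$coef[1, 1, 1], 1)
  expect_lt(m2$p[1, 1, 1], 1e-10)

  # constant voxel -> NaN coefficient and p
  m3 <- spearman_map(series_from_matrix(cbind(rep(1, 5), x)), y)
  expect_true(is.nan(m3$coef[1, 1, 1]) && is.nan(m3$p[1, 1, 1]))
  expect_false(is.nan(m3$coef[2, 1, 1]))

  expect_error(spearman_map(series_from_matrix(cbind(1:3)), 1:3),
               "at least 4")

  # oracle agreement on 100 random voxels (continuous, tie-free)
  set.seed(42)
  M <- matrix(rnorm(30 * 100), 30, 100)
  yy <- rnorm(30)
  mo <- spearman_map(series_from_matrix(M), yy)
  expected <- apply(M, 2, spearman_oracle, y = yy)
  expect_equal(as.numeric(mo$coef), expected, tolerance = 1e-10)
  # and agreement with the t-approximation p-value
  n <- 30
  tstat <- expected * sqrt((n - 2) / (1 - expected^2))
  expect_equal(as.numeric(mo$p), 2 * pt(-abs(tstat), n - 2),
               tolerance = 1e-10)

  # ties handled by average ranks (cross-check against cor())
  Mt <- matrix(sample(1:5, 30 * 20, replace = TRUE), 30, 20)
  yt <- sample(1:4, 30, replace = TRUE)
  mt <- spearman_map(series_from_matrix(Mt), yt)
  expect_equal(as.numeric(mt$coef),
               as.numeric(cor(Mt, yt, method = "spearman")),
               tolerance = 1e-12)

  # listwise deletion per voxel with n recorded
  Mna <- M
  Mna[1:5, 1] <- NA
  mna <- spearman_map(series_from_matrix(Mna), yy)
  expect_identical(mna$n[1, 1, 1], 25L)
  expect_equal(mna$coef[1, 1, 1], spearman_oracle(M[6:30, 1], yy[6:30]),
               tolerance = 1e-10)
})

test_that("partial correlation matches the residualization oracle", {
  set.seed(7)
  n <- 40
  M <- matrix(rnorm(n * 50), n, 50)
  y <- rnorm(n); z <- rnorm(n) + 0.5 * y
  s <- series_from_matrix(M)
  m <- partial_corr_map(s, y, z)
  oracle <- apply(M, 2, function(x)
    cor(resid(lm(x ~ z)), resid(lm(y ~ z))))
  expect_equal(as.numeric(m$coef), oracle, tolerance = 1e-12)

  # z orthogonal to x and y leaves the plain correlation
  x1 <- rnorm(n)
  zo <- resid(lm(rnorm(n) ~ x1 + y))  # orthogonal to both by construction
  mo <- partial_corr_map(series_from_matrix(cbind(x1)), y, zo)
  expect_equal(mo$coef[1, 1, 1], cor(x1, y), tolerance = 1e-10)

  # y fully explained by z
  my <- partial_corr_map(series_from_matrix(cbind(x1)), y, y)
  expect_true(is.nan(my$coef[1, 1, 1]) || abs(my$coef[1, 1, 1]) < 1e-6)

  expect_error(partial_corr_map(series_from_matrix(M[1:4, ]), y[1:4],
                                z[1:4]), "at least 5")
})

test_that("permutation null yields the nominal type-I rate", {
  set.seed(11)
  n <- 100
  M <- matrix(rnorm(n * 3000), n, 3000)
  y <- rnorm(n)
  y_perm <- sample(y)
  m <- spearman_map(series_from_matrix(M), y_perm)
  frac <- mean(m$p < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("cluster filter implements the many-voxel rule", {
  d <- c(6L, 6L, 6L)
  coefa <- array(0.9, d)
  p <- array(1, d)
  p[2, 2, 2] <- 1e-4              # isolated voxel
  p[5, 5, 5] <- 1e-4; p[5, 5, 6] <- 1e-4  # touching pair
  map <- structure(list(coef = coefa, p = p, n = array(10L, d),
                        spacing = c(1, 1, 1), method = "spearman",
                        trait = "t", channel = "volume"),
                   class = "imio_map")
  expect_identical(cluster_filter(map, 1)$p, p)
  f2 <- cluster_filter(map, 2)
  expect_identical(f2$p[2, 2, 2], 1)
  expect_identical(f2$p[5, 5, 5], 1e-4)
  expect_identical(f2$p[5, 5, 6], 1e-4)
  expect_identical(f2$coef, coefa)  # coefficients untouched
  # diagonal contact counts as connected (26-connectivity)
  p3 <- array(1, d); p3[1, 1, 1] <- 1e-4; p3[2, 2, 2] <- 1e-4
  map3 <- map; map3$p <- p3
  f3 <- cluster_filter(map3, 2)
  expect_identical(f3$p[1, 1, 1], 1e-4)
})

test_that("rendering follows the transparency and colormap rules", {
  d <- c(8L, 8L, 8L)
  set.seed(1)
  un <- imio_volume(array(runif(prod(d)), d), c(1, 1, 1))
  base <- structure(list(coef = array(NaN, d), p = array(1, d),
                         n = array(10L, d), spacing = c(1, 1, 1),
                         method = "spearman", trait = "t",
                         channel = "volume"),
                    class = "imio_map")
  # all non-significant: montage equals the grey underlay (R = G = B
  # everywhere left of the colorbar strip)
  rgb0 <- render_map(base, un, axial_z = c(2, 3, 4, 5, 6, 7))
  w <- dim(rgb0)[2]
  pane <- seq_len(w - 16)
  expect_equal(rgb0[, pane, 1], rgb0[, pane, 2])
  expect_equal(rgb0[, pane, 2], rgb0[, pane, 3])

  # a single significant rho = +1 voxel takes the colormap's positive
  # extreme exactly
  m1 <- base
  m1$coef[4, 4, 4] <- 1; m1$p[4, 4, 4] <- 1e-6
  rgb1 <- render_map(m1, un, axial_z = c(2, 3, 4, 5, 6, 7))
  extreme <- as.numeric(jet_inverted(1))
  hit <- abs(rgb1[, pane, 1] - extreme[1]) < 1e-9 &
    abs(rgb1[, pane, 2] - extreme[2]) < 1e-9 &
    abs(rgb1[, pane, 3] - extreme[3]) < 1e-9
  expect_true(any(hit))
  # and that extreme is redder than anything on the strictly negative half
  expect_gt(extreme[1], max(jet_inverted(seq(-1, -0.1, by = 0.1))[, 1]))

  # symmetric +/- coefficients map to colours mirrored about the centre
  cols <- jet_inverted(c(-0.6, 0.6))
  expect_equal(unname(cols[1, c(3, 2, 1)]), unname(cols[2, c(1, 2, 3)]),
               tolerance = 1e-12)

  expect_error(render_map(base, un, axial_z = c(1, 2, 3, 4, 5, 99)),
               "out of range")
  expect_error(render_map(base, un, alpha = 1.5), "alpha")

  # PNG writing
  path <- withr::local_tempfile(fileext = ".png")
  render_map(m1, un, axial_z = c(2, 3, 4, 5, 6, 7), path = path)
  expect_true(file.exists(path) && file.size(path) > 0)
})

test_that("phantom Jacobian series rank-correlates with the linked scales", {
  # one sex stratum: the linking is relative to the sex-stratum median
  coh_all <- small_cohort()
  coh <- coh_all[coh_all$sex == "female", ][seq(1, 40, by = 4), ]
  class(coh) <- class(coh_all)
  specs <- link_phantom_specs(coh, shape = tiny_shape,
                              spacing = tiny_spacing)
  maps <- list()
  for (i in seq_along(specs)) {
    ph <- generate_phantom(specs[[i]], seed = 50 + i)
    maps[[coh$id[i]]] <- jacobian_map(ph$gt_field)
  }
  s <- build_voxel_series(maps, coh, "volume")
  # voxel at the VAT kernel core responds only to the VAT scale
  g <- phantom_geometry(tiny_shape, tiny_spacing)
  core <- round(c(g$abdo_c[1] / tiny_spacing[1],
                  g$abdo_c[2] / tiny_spacing[2],
                  mean(g$abdo_z) / tiny_spacing[3])) + 1
  v <- core[1] + tiny_shape[1] * (core[2] - 1 +
                                    tiny_shape[2] * (core[3] - 1))
  vat_scales <- vapply(specs, function(x) x$scales[["vat"]], 0)
  expect_equal(cor(s$X[, v], vat_scales, method = "spearman"), 1)
  expect_equal(cor(s$X[, v], coh$vat, method = "spearman"), 1)
})
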