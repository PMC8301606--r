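test_that("variable preparation: log transform list and stratified z-scores", {
  coh <- small_cohort()
  prep <- prepare_variables(coh)
  for (sx in c("female", "male")) {
    i <- prep$sex == sx
    # ln applied to exactly the four skewed variables before z-scoring
    expect_equal(prep$vat[i],
                 as.numeric(scale(log(coh$vat[i]))), tolerance = 1e-12)
    lf <- log(pmax(coh$liver_fat[i], 0.01))
    expect_equal(prep$liver_fat[i],
                 as.numeric((lf - mean(lf, na.rm = TRUE)) /
                              sd(lf, na.rm = TRUE)), tolerance = 1e-12)
    # height not ln-transformed
    expect_equal(prep$height[i],
                 as.numeric(scale(coh$height[i])), tolerance = 1e-12)
    # z-scored to mean 0, SD 1 within stratum
    expect_equal(mean(prep$weight[i]), 0, tolerance = 1e-12)
    expect_equal(sd(prep$weight[i]), 1, tolerance = 1e-12)
  }
  bad <- coh
  bad$height <- 170
  expect_error(prepare_variables(bad), "zero-variance")
  expect_error(prepare_variables(coh[0, ]), "empty")
})

test_that("fit_model matches the normal-equations oracle and correlation", {
  coh <- small_cohort()
  # outcome identical to the predictor after standardization
  coh2 <- coh
  coh2$imt <- coh2$weight
  prep2 <- prepare_variables(coh2)
  r <- fit_model(model_spec("imt", "weight", "none", "female"), prep2)
  expect_equal(r$beta, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-12)

  prep <- prepare_variables(coh)
  # unadjusted standardized beta equals the Pearson correlation
  i <- prep$sex == "male"
  r2 <- fit_model(model_spec("imgsm", "vat", "none", "male"), prep)
  expect_equal(r2$beta, cor(prep$imgsm[i], prep$vat[i]), tolerance = 1e-12)
  expect_identical(r2$n, sum(i))
  expect_true(r2$ci_low <= r2$beta && r2$beta <= r2$ci_high)

  # direct (X'X)^-1 X'y oracle for the adjusted model
  r3 <- fit_model(model_spec("imgsm", "vat", "risk_factors", "female"), prep)
  j <- prep$sex == "female"
  X <- cbind(1, prep$vat[j], prep$sbp[j], prep$ldl[j], prep$hdl[j],
             prep$diabetes[j], prep$smoking[j])
  beta_hat <- solve(t(X) %*% X, t(X) %*% prep$imgsm[j])
  expect_equal(r3$beta, beta_hat[2], tolerance = 1e-10)

  # singular design
  coh3 <- coh
  coh3$sbp <- coh3$ldl
  expect_error(fit_model(model_spec("imt", "vat", "risk_factors", "female"),
                         prepare_variables(coh3)), "singular")
})

test_that("large-cohort standardized betas recover the calibrated effects", {
  big <- generate_cohort(10000, 0, default_calibration(), seed = 1)
  prep <- prepare_variables(big)
  b_vat <- fit_model(model_spec("imgsm", "vat", "none", "female"), prep)
  expect_equal(b_vat$beta, -0.41, tolerance = 0.03)
  b_lean <- fit_model(model_spec("imgsm", "lean_total", "none", "female"),
                      prep)
  expect_equal(b_lean$beta, -0.75, tolerance = 0.03)
  # adjustment attenuates when the confounders are coupled to both sides
  b_adj <- fit_model(model_spec("imgsm", "vat", "risk_factors", "female"),
                     prep)
  expect_lt(abs(b_adj$beta), abs(b_vat$beta))
})

test_that("Framingham score: config, monotonicity, linearity", {
  co <- framingham_coefficients()
  zero <- lapply(co, function(s) {
    s[c("ln_age", "ln_chol", "ln_hdl", "ln_sbp", "ln_sbp_treated",
        "smoking", "diabetes")] <- 0
    s$mean_lp <- 0
    s
  })
  z <- framingham(50, "female", 5.2, 1.5, 123, coefs = zero)
  expect_equal(z$lp, 0)
  expect_equal(z$risk, 1 - zero$female$s0)

  a <- framingham(50, c("male", "male"), 5.4, 1.3, 128,
                  smoker = c(FALSE, TRUE))
  expect_gt(a$lp[2], a$lp[1])
  expect_equal(a$lp[2] - a$lp[1], co$male$smoking, tolerance = 1e-12)

  doubled <- co
  doubled$male$smoking <- 2 * co$male$smoking
  b <- framingham(50, "male", 5.4, 1.3, 128, smoker = TRUE,
                  coefs = doubled)
  expect_equal(b$lp - a$lp[1], 2 * co$male$smoking, tolerance = 1e-12)

  expect_error(framingham(-5, "male", 5, 1.3, 120), "positive")
  expect_error(framingham(50, "other", 5, 1.3, 120), "female/male")

  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_framingham_coefficients(co, path)
  expect_equal(read_framingham_coefficients(path), co, tolerance = 1e-12)

  coh <- small_cohort()
  withfr <- add_framingham(coh)
  expect_true(all(is.finite(withfr$framingham)))
})

test_that("association tables mirror the printed layout", {
  coh <- small_cohort()
  tab <- make_association_tables(coh, "imgsm")
  expect_identical(nrow(tab), 17L * 2L * 2L)
  expect_true(all(c("beta", "ci_low", "ci_high", "p", "n") %in% names(tab)))
  done <- tab[tab$note == "", ]
  expect_true(all(done$ci_low <= done$beta & done$beta <= done$ci_high))
  expect_true(all(done$p >= 0 & done$p <= 1))

  # an empty stratum is flagged per cell, the table is still produced
  fem <- coh[coh$sex == "female", ]
  class(fem) <- class(coh)
  tab2 <- make_association_tables(fem, "imt")
  expect_identical(nrow(tab2), 17L * 2L * 2L)
  expect_true(all(tab2$note[tab2$sex == "male"] != ""))
  expect_true(all(is.na(tab2$beta[tab2$sex == "male"])))

  path <- withr::local_tempfile(fileext = ".csv")
  write_association_tables(tab, path)
  hdr <- names(utils::read.csv(path, check.names = FALSE))
  expect_true(all(c("Beta", "95%CI lower", "95%CI higher", "p-value")
                  %in% hdr))
})

test_that("confidence intervals achieve nominal coverage", {
  cal <- default_calibration()
  true_beta <- cal$female$R["imgsm", "vat"]
  covered <- vapply(1:1500, function(s) {
    coh <- generate_cohort(165, 0, cal, seed = 10000 + s)
    prep <- prepare_variables(coh)
    r <- fit_model(model_spec("imgsm", "vat", "none", "female"), prep)
    r$ci_low <= true_beta && true_beta <= r$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})
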