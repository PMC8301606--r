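.imio_outcomes <- c("imt", "imgsm")
.imio_risk_covariates <- c("sbp", "ldl", "hdl", "diabetes", "smoking")

#' Prepare cohort variables for SD-standardized regression
#'
#' Applies the variable preparation used for the association tables: the
#' right-skewed variables (liver fat, pancreas fat, VAT, SAT) are
#' ln-transformed (after a `max(x, eps)` guard), and all body-composition
#' predictors and both outcomes (IMT, IM-GSM) are z-scored within sex
#' stratum so that regression coefficients are on an SD-per-SD scale.
#' Derived BMI and waist/hip ratio are standardized like any other
#' predictor; risk-factor covariates are left on their natural scale.
#'
#' @param cohort an `imio_cohort`.
#' @param eps positive floor applied before the log transform (default 0.01
#'   unit, guarding near-zero fat fractions).
#' @return Data frame with the same rows, transformed/standardized columns,
#'   class `imio_prepared`.
#' @export
prepare_variables <- function(cohort, eps = 0.01) {
  if (!nrow(cohort)) stop("cohort is empty")
  out <- as.data.frame(cohort)
  for (nm in .imio_lognormal_vars) out[[nm]] <- log(pmax(out[[nm]], eps))
  zcols <- c(.imio_outcomes, .imio_predictors)
  for (sx in unique(out$sex)) {
    idx <- out$sex == sx
    for (nm in zcols) {
      v <- out[[nm]][idx]
      m <- mean(v, na.rm = TRUE)
      s <- sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0)
        stop("zero-variance variable in stratum ", sx, ": ", nm)
      out[[nm]][idx] <- (v - m) / s
    }
  }
  class(out) <- c("imio_prepared", "data.frame")
  out
}

#' Specify one association model
#'
#' @param outcome `"imt"` or `"imgsm"`.
#' @param predictor one body-composition variable of the table roster.
#' @param adjustment `"none"`, `"risk_factors"` (systolic blood pressure,
#'   LDL- and HDL-cholesterol, diabetes, smoking) or `"framingham"` (the
#'   composite score as single covariate).
#' @param sex stratum, `"female"` or `"male"`.
#' @return A `imio_model_spec` list.
#' @export
model_spec <- function(outcome, predictor, adjustment = "none", sex) {
  outcome <- match.arg(outcome, .imio_outcomes)
  adjustment <- match.arg(adjustment, c("none", "risk_factors", "framingham"))
  sex <- match.arg(sex, c("female", "male"))
  if (!predictor %in% .imio_predictors)
    stop("unknown predictor: ", predictor)
  structure(list(outcome = outcome, predictor = predictor,
                 adjustment = adjustment, sex = sex),
            class = "imio_model_spec")
}

#' Fit one SD-standardized association model
#'
#' Ordinary least squares of the (standardized) outcome on the
#' (standardized) predictor within one sex stratum, optionally adjusted.
#' With both sides z-scored the unadjusted coefficient equals the Pearson
#' correlation. Subjects with any missing model variable are dropped
#' (listwise deletion) and the n used is recorded.
#'
#' @param spec an `imio_model_spec`.
#' @param prepared output of [prepare_variables()]. For
#'   `adjustment = "framingham"` it must carry a `framingham` column (see
#'   [framingham()]).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return List of class `imio_regression`: `beta`, `ci_low`, `ci_high`,
#'   `p`, `n`, plus the spec.
#' @export
fit_model <- function(spec, prepared, conf_level = 0.95) {
  stopifnot(inherits(spec, "imio_model_spec"))
  covars <- switch(spec$adjustment,
                   none = character(0),
                   risk_factors = .imio_risk_covariates,
                   framingham = "framingham")
  need <- c(spec$outcome, spec$predictor, covars)
  missing_cols <- setdiff(need, names(prepared))
  if (length(missing_cols))
    stop("prepared table lacks columns: ", paste(missing_cols, collapse = ", "))
  d <- prepared[prepared$sex == spec$sex, need, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(covars) + 2)
    stop("too few complete observations in stratum ", spec$sex)
  fml <- stats::reformulate(c(spec$predictor, covars),
                            response = spec$outcome)
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) stop("singular design in model fit")
  est <- summary(fit)$coefficients[spec$predictor, ]
  tcrit <- qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  out <- list(beta = unname(est["Estimate"]),
              ci_low = unname(est["Estimate"] - tcrit * est["Std. Error"]),
              ci_high = unname(est["Estimate"] + tcrit * est["Std. Error"]),
              p = unname(est["Pr(>|t|)"]),
              n = n, spec = spec)
  class(out) <- "imio_regression"
  out
}

#' @export
print.imio_regression <- function(x, ...) {
  cat(sprintf("%s ~ %s [%s, %s]: beta %.3f (95%% CI %.3f to %.3f), p = %.3g, n = %d\n",
              x$spec$outcome, x$spec$predictor, x$spec$sex,
              x$spec$adjustment, x$beta, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' Framingham general cardiovascular risk score
#'
#' Sex-specific Cox-model linear predictor and 10-year risk of the 2008
#' general-CVD Framingham formulation, with a configurable coefficient
#' table. Risk is `1 - S0 ^ exp(lp - mean_lp)` with the sex-specific
#' baseline survival `S0` and population mean linear predictor.
#'
#' @param age years (> 0).
#' @param sex `"female"`/`"male"` (vectorized).
#' @param chol,hdl total and HDL cholesterol (mmol/l, converted internally
#'   to the log scale the coefficients expect).
#' @param sbp systolic blood pressure (mmHg).
#' @param bp_treated,smoker,diabetic logical/0-1 flags.
#' @param coefs coefficient table, see [framingham_coefficients()].
#' @return List with vectors `lp` (linear predictor) and `risk` (10-year).
#' @export
framingham <- function(age, sex, chol, hdl, sbp, bp_treated = FALSE,
                       smoker = FALSE, diabetic = FALSE,
                       coefs = framingham_coefficients()) {
  n <- max(length(age), length(sex), length(chol), length(hdl), length(sbp))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  chol <- rep_len(chol, n); hdl <- rep_len(hdl, n); sbp <- rep_len(sbp, n)
  bp_treated <- rep_len(as.logical(bp_treated), n)
  smoker <- rep_len(as.numeric(smoker), n)
  diabetic <- rep_len(as.numeric(diabetic), n)
  if (any(!sex %in% c("female", "male"))) stop("sex must be female/male")
  if (any(age <= 0) || any(chol <= 0) || any(hdl <= 0) || any(sbp <= 0))
    stop("age, cholesterol and blood pressure must be positive")
  lp <- numeric(n); risk <- numeric(n)
  for (sx in c("female", "male")) {
    i <- sex == sx
    if (!any(i)) next
    co <- coefs[[sx]]
    lpi <- co$ln_age * log(age[i]) +
      co$ln_chol * log(chol[i]) +
      co$ln_hdl * log(hdl[i]) +
      ifelse(bp_treated[i], co$ln_sbp_treated, co$ln_sbp) * log(sbp[i]) +
      co$smoking * smoker[i] +
      co$diabetes * diabetic[i]
    lp[i] <- lpi
    risk[i] <- 1 - co$s0^exp(lpi - co$mean_lp)
  }
  list(lp = lp, risk = risk)
}

#' Default Framingham coefficient table (2008 general-CVD Cox model)
#'
#' @return Named list with `female`/`male` coefficient sets (`ln_age`,
#'   `ln_chol`, `ln_hdl`, `ln_sbp`, `ln_sbp_treated`, `smoking`,
#'   `diabetes`, `mean_lp`, `s0`).
#' @export
framingham_coefficients <- function() {
  list(
    female = list(ln_age = 2.32888, ln_chol = 1.20904, ln_hdl = -0.70833,
                  ln_sbp = 2.76157, ln_sbp_treated = 2.82263,
                  smoking = 0.52873, diabetes = 0.69154,
                  mean_lp = 26.1931, s0 = 0.95012),
    male = list(ln_age = 3.06117, ln_chol = 1.12370, ln_hdl = -0.93263,
                ln_sbp = 1.93303, ln_sbp_treated = 1.99881,
                smoking = 0.65451, diabetes = 0.57367,
                mean_lp = 23.9802, s0 = 0.88936)
  )
}

#' Read / write a Framingham coefficient table as JSON
#' @param coefs coefficient table as from [framingham_coefficients()].
#' @param path file path.
#' @export
write_framingham_coefficients <- function(coefs, path) {
  jsonlite::write_json(coefs, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_framingham_coefficients
#' @export
read_framingham_coefficients <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Attach the Framingham score to a cohort
#'
#' All subjects of this cohort design are aged 50 and untreated for blood
#' pressure unless stated otherwise.
#'
#' @param cohort an `imio_cohort` (natural-scale, not prepared).
#' @param age assumed age in years (default 50).
#' @param coefs coefficient table.
#' @return The cohort with a `framingham` column (linear predictor).
#' @export
add_framingham <- function(cohort, age = 50,
                           coefs = framingham_coefficients()) {
  fr <- framingham(age = age, sex = cohort$sex, chol = cohort$chol,
                   hdl = cohort$hdl, sbp = cohort$sbp,
                   smoker = cohort$smoking, diabetic = cohort$diabetes,
                   coefs = coefs)
  cohort$framingham <- fr$lp
  cohort
}

#' Sex-stratified association tables
#'
#' Fits the full predictor roster (17 body-composition variables) for one
#' outcome, per sex stratum, unadjusted and adjusted for the risk-factor
#' set, mirroring the published table layout. Fit errors in a cell are
#' recorded (NA estimates) without aborting the table.
#'
#' @param cohort an `imio_cohort` (natural scale; prepared internally).
#' @param outcome `"imt"` or `"imgsm"`.
#' @param adjustments character subset of `c("none", "risk_factors")`.
#' @return Data frame with columns `predictor`, `sex`, `adjustment`,
#'   `beta`, `ci_low`, `ci_high`, `p`, `n`, `note`.
#' @export
make_association_tables <- function(cohort, outcome,
                                    adjustments = c("none", "risk_factors")) {
  outcome <- match.arg(outcome, .imio_outcomes)
  prepared <- prepare_variables(cohort)
  grid <- expand.grid(predictor = .imio_predictors,
                      sex = c("male", "female"),
                      adjustment = adjustments, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    res <- tryCatch(
      fit_model(model_spec(outcome, g$predictor, g$adjustment, g$sex),
                prepared),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(predictor = g$predictor, sex = g$sex,
                 adjustment = g$adjustment, beta = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                 n = NA_integer_, note = conditionMessage(res))
    } else {
      data.frame(predictor = g$predictor, sex = g$sex,
                 adjustment = g$adjustment, beta = res$beta,
                 ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
                 n = res$n, note = "")
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "outcome") <- outcome
  out
}

#' Write an association table as CSV in the printed column layout
#'
#' @param tab output of [make_association_tables()].
#' @param path file path.
#' @export
write_association_tables <- function(tab, path) {
  out <- tab
  names(out)[names(out) == "beta"] <- "Beta"
  names(out)[names(out) == "ci_low"] <- "95%CI lower"
  names(out)[names(out) == "ci_high"] <- "95%CI higher"
  names(out)[names(out) == "p"] <- "p-value"
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
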