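#' @useDynLib imiomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm qnorm pnorm sd cor median quantile lm coef confint
#'   pt qt complete.cases setNames
NULL

# Cohort variables on the latent (Gaussian-copula) scale, in draw order.
# Log-normal variables are represented by their natural logarithm.
.imio_latent_vars <- c(
  "imt", "imgsm",
  "sbp", "dbp", "glucose", "chol", "ldl", "hdl",
  "smoking", "diabetes",
  "height", "weight", "waist", "hip",
  "fat_total", "lean_total", "fat_trunk", "fat_leg", "lean_leg",
  "fat_arm", "lean_arm",
  "liver_fat", "pancreas_fat", "vat", "sat"
)

.imio_lognormal_vars <- c("liver_fat", "pancreas_fat", "vat", "sat")

# Body-composition predictor roster of the association tables (17 rows).
.imio_predictors <- c(
  "height", "weight", "waist", "hip", "bmi", "whr",
  "fat_total", "lean_total", "fat_trunk", "fat_leg", "lean_leg",
  "fat_arm", "lean_arm", "liver_fat", "pancreas_fat", "vat", "sat"
)

.imio_units <- c(
  imt = "mm", imgsm = "GSU (0-256)", sbp = "mmHg", dbp = "mmHg",
  glucose = "mmol/l", chol = "mmol/l", ldl = "mmol/l", hdl = "mmol/l",
  smoking = "binary", diabetes = "binary",
  height = "cm", weight = "kg", waist = "cm", hip = "cm",
  fat_total = "kg", lean_total = "kg", fat_trunk = "kg", fat_leg = "kg",
  lean_leg = "kg", fat_arm = "kg", lean_arm = "kg",
  liver_fat = "%", pancreas_fat = "%", vat = "L", sat = "L"
)

#' Default cohort calibration
#'
#' Returns the calibration used by [generate_cohort()]: per-sex marginal
#' means and SDs for every cohort variable (natural units), the set of
#' right-skewed variables modelled as log-normal, per-sex target correlation
#' matrices on the transformed (ln where applicable) scale, and per-sex
#' smoking/diabetes prevalences. The marginals reproduce the published
#' sex-stratified characteristics of a 50-year-old population cohort (e.g.
#' female mean IMT 0.62 mm, SD 0.11; male mean VAT 4.4 L, SD 2.2); the
#' correlation targets encode the sex-stratified standardized associations
#' between the carotid wall measures and body composition (e.g. female
#' IM-GSM vs ln VAT -0.41, IM-GSM vs total lean mass -0.75, male IMT vs
#' total lean mass +0.32), with near-zero entries where associations were
#' non-significant. Pairwise targets are assembled into a full matrix and
#' repaired to the nearest positive semi-definite correlation matrix.
#'
#' @return An object of class `imio_calibration`: a list with elements
#'   `variables` (latent variable names), `lognormal` (names treated as
#'   log-normal), and `female`/`male`, each containing `mean`, `sd` (named,
#'   natural scale), `R` (correlation matrix on the transformed scale),
#'   `smoking_prev`, `diabetes_prev`.
#' @examples
#' cal <- default_calibration()
#' cal$female$mean[["imt"]]   # 0.62 mm
#' cal$male$mean[["vat"]]     # 4.4 L
#' @export
default_calibration <- function() {
  female_mean <- c(
    imt = 0.62, imgsm = 68.1, sbp = 123.4, dbp = 74.2, glucose = 4.5,
    chol = 5.2, ldl = 3.3, hdl = 1.5, smoking = 0, diabetes = 0,
    height = 166.2, weight = 71.8, waist = 89.6, hip = 103.1,
    fat_total = 26.6, lean_total = 42.3, fat_trunk = 13.5, fat_leg = 9.5,
    lean_leg = 13.7, fat_arm = 2.8, lean_arm = 4.6,
    liver_fat = 3.4, pancreas_fat = 4.3, vat = 2.5, sat = 7.6
  )
  female_sd <- c(
    imt = 0.11, imgsm = 15, sbp = 17, dbp = 9.9, glucose = 0.5,
    chol = 0.9, ldl = 0.8, hdl = 0.3, smoking = 1, diabetes = 1,
    height = 6.6, weight = 12.6, waist = 11.1, hip = 8.4,
    fat_total = 9.8, lean_total = 4.7, fat_trunk = 5.5, fat_leg = 3.4,
    lean_leg = 1.8, fat_arm = 1.2, lean_arm = 0.7,
    liver_fat = 5.7, pancreas_fat = 3, vat = 1.5, sat = 3.4
  )
  male_mean <- c(
    imt = 0.66, imgsm = 66.6, sbp = 127.8, dbp = 79.1, glucose = 4.6,
    chol = 5.4, ldl = 3.5, hdl = 1.3, smoking = 0, diabetes = 0,
    height = 179.2, weight = 85.7, waist = 94.5, hip = 101.1,
    fat_total = 21.8, lean_total = 60.1, fat_trunk = 13.5, fat_leg = 5.7,
    lean_leg = 20.1, fat_arm = 1.9, lean_arm = 7.8,
    liver_fat = 5, pancreas_fat = 7.1, vat = 4.4, sat = 5.7
  )
  male_sd <- c(
    imt = 0.12, imgsm = 15.3, sbp = 15.9, dbp = 10.7, glucose = 0.8,
    chol = 1.1, ldl = 0.9, hdl = 0.4, smoking = 1, diabetes = 1,
    height = 6.3, weight = 11.9, waist = 10, hip = 6.3,
    fat_total = 8.8, lean_total = 5.9, fat_trunk = 5.7, fat_leg = 2.3,
    lean_leg = 2.3, fat_arm = 0.9, lean_arm = 1.1,
    liver_fat = 5.7, pancreas_fat = 6.4, vat = 2.2, sat = 2.8
  )

  # Pairwise correlations shared by both sexes: the predictor/risk-factor
  # block, chosen as physiologically plausible values (only the outcome
  # rows have published counterparts).
  common <- list(
    # anthropometry
    c("height", "weight", 0.45), c("height", "waist", 0.15),
    c("height", "hip", 0.20), c("weight", "waist", 0.80),
    c("weight", "hip", 0.78), c("waist", "hip", 0.72),
    # fat compartments
    c("fat_total", "fat_trunk", 0.95), c("fat_total", "fat_leg", 0.85),
    c("fat_total", "fat_arm", 0.90), c("fat_trunk", "fat_leg", 0.68),
    c("fat_trunk", "fat_arm", 0.85), c("fat_leg", "fat_arm", 0.75),
    # lean compartments
    c("lean_total", "lean_leg", 0.95), c("lean_total", "lean_arm", 0.92),
    c("lean_leg", "lean_arm", 0.85),
    # fat vs lean
    c("fat_total", "lean_total", 0.35), c("fat_total", "lean_leg", 0.33),
    c("fat_total", "lean_arm", 0.35), c("fat_trunk", "lean_total", 0.33),
    c("fat_trunk", "lean_leg", 0.30), c("fat_trunk", "lean_arm", 0.33),
    c("fat_leg", "lean_total", 0.30), c("fat_leg", "lean_leg", 0.33),
    c("fat_leg", "lean_arm", 0.28), c("fat_arm", "lean_total", 0.35),
    c("fat_arm", "lean_leg", 0.32), c("fat_arm", "lean_arm", 0.40),
    # anthropometry vs compartments
    c("weight", "fat_total", 0.85), c("weight", "lean_total", 0.60),
    c("weight", "fat_trunk", 0.82), c("weight", "fat_leg", 0.70),
    c("weight", "lean_leg", 0.58), c("weight", "fat_arm", 0.78),
    c("weight", "lean_arm", 0.58),
    c("waist", "fat_total", 0.82), c("waist", "fat_trunk", 0.88),
    c("waist", "fat_leg", 0.58), c("waist", "fat_arm", 0.72),
    c("waist", "lean_total", 0.35), c("waist", "lean_leg", 0.32),
    c("waist", "lean_arm", 0.35),
    c("hip", "fat_total", 0.80), c("hip", "fat_trunk", 0.70),
    c("hip", "fat_leg", 0.78), c("hip", "fat_arm", 0.65),
    c("hip", "lean_total", 0.35), c("hip", "lean_leg", 0.35),
    c("hip", "lean_arm", 0.32),
    c("height", "fat_total", 0.05), c("height", "fat_trunk", 0.03),
    c("height", "fat_leg", 0.08), c("height", "fat_arm", 0.02),
    c("height", "lean_total", 0.60), c("height", "lean_leg", 0.60),
    c("height", "lean_arm", 0.52),
    # MRI depots / ectopic fat (ln scale)
    c("vat", "waist", 0.78), c("vat", "fat_trunk", 0.80),
    c("vat", "fat_total", 0.72), c("vat", "weight", 0.68),
    c("vat", "hip", 0.55), c("vat", "fat_leg", 0.45),
    c("vat", "fat_arm", 0.65), c("vat", "lean_total", 0.30),
    c("vat", "lean_leg", 0.27), c("vat", "lean_arm", 0.32),
    c("vat", "sat", 0.58), c("vat", "height", 0.05),
    c("sat", "fat_total", 0.88), c("sat", "fat_trunk", 0.82),
    c("sat", "fat_leg", 0.78), c("sat", "fat_arm", 0.75),
    c("sat", "hip", 0.78), c("sat", "waist", 0.72),
    c("sat", "weight", 0.72), c("sat", "lean_total", 0.22),
    c("sat", "lean_leg", 0.20), c("sat", "lean_arm", 0.22),
    c("sat", "height", 0.00),
    c("liver_fat", "vat", 0.58), c("liver_fat", "sat", 0.38),
    c("liver_fat", "fat_total", 0.42), c("liver_fat", "fat_trunk", 0.48),
    c("liver_fat", "waist", 0.48), c("liver_fat", "weight", 0.42),
    c("liver_fat", "hip", 0.30), c("liver_fat", "fat_leg", 0.25),
    c("liver_fat", "fat_arm", 0.40), c("liver_fat", "lean_total", 0.18),
    c("liver_fat", "lean_leg", 0.16), c("liver_fat", "lean_arm", 0.20),
    c("liver_fat", "pancreas_fat", 0.45),
    c("pancreas_fat", "vat", 0.48), c("pancreas_fat", "sat", 0.32),
    c("pancreas_fat", "fat_total", 0.35), c("pancreas_fat", "fat_trunk", 0.40),
    c("pancreas_fat", "waist", 0.40), c("pancreas_fat", "weight", 0.35),
    c("pancreas_fat", "hip", 0.25), c("pancreas_fat", "fat_leg", 0.20),
    c("pancreas_fat", "fat_arm", 0.32), c("pancreas_fat", "lean_total", 0.15),
    c("pancreas_fat", "lean_leg", 0.13), c("pancreas_fat", "lean_arm", 0.17),
    # risk factors
    c("sbp", "dbp", 0.70), c("chol", "ldl", 0.90), c("chol", "hdl", 0.15),
    c("ldl", "hdl", -0.05), c("chol", "glucose", 0.10),
    c("sbp", "weight", 0.28), c("sbp", "waist", 0.28), c("sbp", "vat", 0.30),
    c("sbp", "fat_total", 0.24), c("sbp", "fat_trunk", 0.26),
    c("sbp", "glucose", 0.20), c("dbp", "weight", 0.24),
    c("dbp", "waist", 0.24), c("dbp", "vat", 0.26),
    c("glucose", "vat", 0.40), c("glucose", "waist", 0.32),
    c("glucose", "weight", 0.26), c("glucose", "liver_fat", 0.35),
    c("glucose", "fat_trunk", 0.28), c("glucose", "diabetes", 0.60),
    c("hdl", "vat", -0.45), c("hdl", "fat_trunk", -0.35),
    c("hdl", "waist", -0.35), c("hdl", "weight", -0.28),
    c("hdl", "liver_fat", -0.30), c("hdl", "fat_total", -0.25),
    c("ldl", "vat", 0.20), c("ldl", "waist", 0.18), c("ldl", "weight", 0.15),
    c("chol", "vat", 0.15), c("chol", "waist", 0.12),
    c("smoking", "hdl", -0.10), c("smoking", "weight", -0.05),
    c("diabetes", "vat", 0.30), c("diabetes", "waist", 0.25),
    c("diabetes", "weight", 0.22), c("diabetes", "liver_fat", 0.28),
    c("diabetes", "fat_trunk", 0.22), c("diabetes", "sbp", 0.15),
    c("diabetes", "hdl", -0.20)
  )

  # Outcome rows: unadjusted sex-stratified standardized coefficients of the
  # published association tables, read as correlations (both sides
  # standardized); plus plausible outcome-risk-factor correlations.
  female_rows <- list(
    c("imt", "imgsm", -0.10),
    # IMT row (female)
    c("imt", "height", 0.18), c("imt", "weight", 0.15),
    c("imt", "waist", 0.12), c("imt", "hip", 0.05),
    c("imt", "fat_total", 0.09), c("imt", "lean_total", 0.36),
    c("imt", "fat_trunk", 0.10), c("imt", "fat_leg", 0.06),
    c("imt", "lean_leg", 0.27), c("imt", "fat_arm", 0.10),
    c("imt", "lean_arm", 0.42), c("imt", "liver_fat", 0.16),
    c("imt", "pancreas_fat", 0.13), c("imt", "vat", 0.14),
    c("imt", "sat", 0.10),
    # IM-GSM row (female)
    c("imgsm", "height", -0.10), c("imgsm", "weight", -0.38),
    c("imgsm", "waist", -0.29), c("imgsm", "hip", -0.23),
    c("imgsm", "fat_total", -0.31), c("imgsm", "lean_total", -0.75),
    c("imgsm", "fat_trunk", -0.37), c("imgsm", "fat_leg", -0.21),
    c("imgsm", "lean_leg", -0.62), c("imgsm", "fat_arm", -0.33),
    c("imgsm", "lean_arm", -0.74), c("imgsm", "liver_fat", -0.24),
    c("imgsm", "pancreas_fat", -0.29), c("imgsm", "vat", -0.41),
    c("imgsm", "sat", -0.36),
    # risk factors
    c("imt", "sbp", 0.25), c("imt", "dbp", 0.18), c("imt", "ldl", 0.20),
    c("imt", "chol", 0.12), c("imt", "glucose", 0.10), c("imt", "hdl", -0.05),
    c("imt", "smoking", 0.05), c("imt", "diabetes", 0.08),
    c("imgsm", "sbp", -0.15), c("imgsm", "dbp", -0.10),
    c("imgsm", "ldl", -0.08), c("imgsm", "chol", -0.05),
    c("imgsm", "glucose", -0.20), c("imgsm", "hdl", 0.20),
    c("imgsm", "smoking", -0.05), c("imgsm", "diabetes", -0.12)
  )
  male_rows <- list(
    c("imt", "imgsm", -0.10),
    # IMT row (male)
    c("imt", "height", 0.20), c("imt", "weight", 0.16),
    c("imt", "waist", 0.08), c("imt", "hip", 0.10),
    c("imt", "fat_total", 0.03), c("imt", "lean_total", 0.32),
    c("imt", "fat_trunk", 0.03), c("imt", "fat_leg", -0.02),
    c("imt", "lean_leg", 0.27), c("imt", "fat_arm", 0.12),
    c("imt", "lean_arm", 0.30), c("imt", "liver_fat", 0.14),
    c("imt", "pancreas_fat", 0.02), c("imt", "vat", 0.10),
    c("imt", "sat", 0.07),
    # IM-GSM row (male)
    c("imgsm", "height", -0.04), c("imgsm", "weight", -0.32),
    c("imgsm", "waist", -0.26), c("imgsm", "hip", -0.28),
    c("imgsm", "fat_total", -0.25), c("imgsm", "lean_total", -0.33),
    c("imgsm", "fat_trunk", -0.24), c("imgsm", "fat_leg", -0.22),
    c("imgsm", "lean_leg", -0.25), c("imgsm", "fat_arm", -0.35),
    c("imgsm", "lean_arm", -0.40), c("imgsm", "liver_fat", -0.13),
    c("imgsm", "pancreas_fat", -0.13), c("imgsm", "vat", -0.31),
    c("imgsm", "sat", -0.23),
    # risk factors
    c("imt", "sbp", 0.25), c("imt", "dbp", 0.18), c("imt", "ldl", 0.20),
    c("imt", "chol", 0.12), c("imt", "glucose", 0.10), c("imt", "hdl", -0.05),
    c("imt", "smoking", 0.05), c("imt", "diabetes", 0.08),
    c("imgsm", "sbp", -0.15), c("imgsm", "dbp", -0.10),
    c("imgsm", "ldl", -0.08), c("imgsm", "chol", -0.05),
    c("imgsm", "glucose", -0.18), c("imgsm", "hdl", 0.18),
    c("imgsm", "smoking", -0.05), c("imgsm", "diabetes", -0.10)
  )

  build_R <- function(rows) {
    v <- .imio_latent_vars
    R <- diag(length(v))
    dimnames(R) <- list(v, v)
    for (p in c(common, rows)) {
      i <- p[[1]]; j <- p[[2]]; r <- as.numeric(p[[3]])
      R[i, j] <- r
      R[j, i] <- r
    }
    # Weight the outcome rows heavily so the repair preserves the published
    # standardized associations and adjusts the invented predictor block.
    w <- setNames(rep(1, length(v)), v)
    w[c("imt", "imgsm")] <- 100
    nearest_psd_correlation(R, weights = w)
  }

  out <- list(
    variables = .imio_latent_vars,
    lognormal = .imio_lognormal_vars,
    units = .imio_units,
    female = list(
      mean = female_mean, sd = female_sd, R = build_R(female_rows),
      smoking_prev = 0.044, diabetes_prev = 0.03,
      liver_missing_frac = 27 / 165
    ),
    male = list(
      mean = male_mean, sd = male_sd, R = build_R(male_rows),
      smoking_prev = 0.146, diabetes_prev = 0.03,
      liver_missing_frac = 35 / 156
    )
  )
  class(out) <- "imio_calibration"
  validate_calibration(out)
  out
}

#' Repair a symmetric matrix to the nearest positive semi-definite
#' correlation matrix
#'
#' Higham's alternating-projection algorithm (with Dykstra correction) in a
#' diagonally weighted Frobenius norm. With unit weights this is the plain
#' nearest correlation matrix (cross-checked against [Matrix::nearPD()]);
#' larger row weights keep the corresponding rows closer to their targets,
#' moving the repair onto the lightly weighted block. Returns the input
#' unchanged when it is already positive semi-definite.
#'
#' @param R square symmetric matrix with unit diagonal.
#' @param weights positive per-variable weights (length `nrow(R)`); the
#'   effective elementwise weight on entry (i,j) is `sqrt(w_i * w_j)`.
#' @param maxit,tol iteration cap and convergence tolerance.
#' @return A valid correlation matrix (base matrix) with the same dimnames.
#' @export
nearest_psd_correlation <- function(R, weights = NULL, maxit = 2000,
                                    tol = 1e-9) {
  if (!isSymmetric(unname(R), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= 1e-8) return(R)
  n <- nrow(R)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    stop("weights must be positive, one per variable")
  W <- sqrt(weights)
  WW <- outer(W, W)
  Y <- R
  dS <- matrix(0, n, n)
  for (it in seq_len(maxit)) {
    Rk <- Y - dS
    e <- eigen(WW * Rk, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    X <- (e$vectors %*% (lam * t(e$vectors))) / WW
    dS <- X - Rk
    Yold <- Y
    Y <- X
    diag(Y) <- 1
    if (max(abs(Y - Yold)) < tol &&
        min(eigen(Y, symmetric = TRUE, only.values = TRUE)$values) > -1e-8)
      break
  }
  Y <- (Y + t(Y)) / 2
  # lift any residual tiny negative eigenvalue
  e <- eigen(Y, symmetric = TRUE)
  if (min(e$values) < 0) {
    Y <- e$vectors %*% (pmax(e$values, 1e-10) * t(e$vectors))
    D <- sqrt(diag(Y))
    Y <- Y / outer(D, D)
  }
  dimnames(Y) <- dimnames(R)
  Y
}

validate_calibration <- function(cal) {
  stopifnot(inherits(cal, "imio_calibration"))
  for (sx in c("female", "male")) {
    s <- cal[[sx]]
    if (any(s$sd <= 0)) stop("calibration SDs must be positive")
    R <- s$R
    if (!isSymmetric(unname(R), tol = 1e-8))
      stop("calibration correlation matrix must be symmetric")
    if (any(abs(diag(R) - 1) > 1e-8))
      stop("calibration correlation matrix must have unit diagonal")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6)
      stop("calibration correlation matrix is not positive semi-definite")
  }
  invisible(cal)
}

#' @export
print.imio_calibration <- function(x, ...) {
  cat("Cohort calibration:", length(x$variables), "latent variables\n")
  cat("  log-normal:", paste(x$lognormal, collapse = ", "), "\n")
  for (sx in c("female", "male")) {
    cat(sprintf("  %s: mean IMT %.2f mm, IM-GSM %.1f, VAT %.1f L; smoking %.1f%%\n",
                sx, x[[sx]]$mean[["imt"]], x[[sx]]$mean[["imgsm"]],
                x[[sx]]$mean[["vat"]], 100 * x[[sx]]$smoking_prev))
  }
  invisible(x)
}

#' Write / read a calibration as JSON
#'
#' @param cal an `imio_calibration` object.
#' @param path file path.
#' @return `read_calibration` returns an `imio_calibration`;
#'   `write_calibration` returns `path` invisibly.
#' @export
write_calibration <- function(cal, path) {
  validate_calibration(cal)
  x <- unclass(cal)
  x$units <- as.list(x$units)
  for (sx in c("female", "male")) {
    x[[sx]]$R <- as.data.frame(x[[sx]]$R)
    x[[sx]]$mean <- as.list(x[[sx]]$mean)
    x[[sx]]$sd <- as.list(x[[sx]]$sd)
  }
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (sx in c("female", "male")) {
    R <- as.matrix(x[[sx]]$R)
    dimnames(R) <- list(x$variables, x$variables)
    x[[sx]]$R <- R
    x[[sx]]$mean <- unlist(x[[sx]]$mean)
    x[[sx]]$sd <- unlist(x[[sx]]$sd)
  }
  x$units <- unlist(x$units)
  class(x) <- "imio_calibration"
  validate_calibration(x)
  x
}
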