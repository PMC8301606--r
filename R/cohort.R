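# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  force(code)
}

lognormal_params <- function(m, s) {
  # natural-scale mean m and SD s -> (mu, sigma) of ln X, so that the
  # arithmetic mean of exp(N(mu, sigma^2)) equals m
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

.imio_cohort_cols <- c(
  "id", "sex", "imt", "imgsm", "sbp", "dbp", "glucose", "chol", "ldl",
  "hdl", "smoking", "diabetes", "height", "weight", "waist", "hip",
  "bmi", "whr", "fat_total", "lean_total", "fat_trunk", "fat_leg",
  "lean_leg", "fat_arm", "lean_arm", "liver_fat", "pancreas_fat",
  "vat", "sat", "liver_scan_missing"
)

#' Generate a calibrated synthetic cohort
#'
#' Draws a sex-stratified cohort from the Gaussian-copula calibration: a
#' per-sex multivariate normal on the transformed scale (natural log for the
#' right-skewed liver fat, pancreas fat, VAT and SAT), exponentiated back for
#' the log-normal variables, with BMI (kg/m^2) and waist/hip ratio derived
#' deterministically and smoking/diabetes obtained by thresholding their
#' latent Gaussian components at the calibrated prevalence. Liver and
#' pancreas fat are set missing (`NA`, flag `liver_scan_missing`) for the
#' first subjects of each stratum at the calibrated per-sex rate, emulating
#' the subset of the cohort that was scanned before the dedicated liver
#' protocol was added.
#'
#' The log-normal parameters are chosen so that the arithmetic (natural
#' scale) mean and SD match the calibration, so sample means are directly
#' comparable with published cohort characteristics.
#'
#' @param n_female,n_male stratum sizes (non-negative integers).
#' @param calib an `imio_calibration`, e.g. [default_calibration()].
#' @param seed integer seed; fixed seed gives a bit-identical cohort.
#' @return An `imio_cohort` data frame with one row per subject.
#' @examples
#' coh <- generate_cohort(165, 156, default_calibration(), seed = 1)
#' mean(coh$imt[coh$sex == "female"])
#' @export
generate_cohort <- function(n_female, n_male, calib = default_calibration(),
                            seed = 1) {
  if (!is.numeric(n_female) || !is.numeric(n_male) ||
      n_female < 0 || n_male < 0)
    stop("stratum sizes must be non-negative")
  validate_calibration(calib)
  n_female <- as.integer(n_female); n_male <- as.integer(n_male)

  draw_stratum <- function(n, sx) {
    s <- calib[[sx]]
    v <- calib$variables
    p <- length(v)
    Z <- matrix(rnorm(n * p), nrow = n, ncol = p)
    ev <- eigen(s$R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6) stop("calibration correlation matrix is not PSD")
    L <- chol(s$R + diag(1e-8, p))
    Z <- Z %*% L
    colnames(Z) <- v
    out <- data.frame(row.names = seq_len(max(n, 0)))
    for (nm in v) {
      z <- Z[, nm]
      if (nm %in% calib$lognormal) {
        lp <- lognormal_params(s$mean[[nm]], s$sd[[nm]])
        out[[nm]] <- exp(lp$mu + lp$sigma * z)
      } else if (nm == "smoking") {
        out[[nm]] <- as.integer(z > qnorm(1 - s$smoking_prev))
      } else if (nm == "diabetes") {
        out[[nm]] <- as.integer(z > qnorm(1 - s$diabetes_prev))
      } else {
        out[[nm]] <- s$mean[[nm]] + s$sd[[nm]] * z
      }
    }
    # physical range guards (affect only extreme tail draws)
    positive <- c("imt", "sbp", "dbp", "glucose", "chol", "ldl", "hdl",
                  "height", "weight", "waist", "hip", "fat_total",
                  "lean_total", "fat_trunk", "fat_leg", "lean_leg",
                  "fat_arm", "lean_arm")
    for (nm in positive) out[[nm]] <- pmax(out[[nm]], 0.01)
    out$imgsm <- pmin(pmax(out$imgsm, 0), 256)
    out$sex <- sx
    out$bmi <- out$weight / (out$height / 100)^2
    out$whr <- out$waist / out$hip
    n_missing <- ceiling(n * s$liver_missing_frac)
    out$liver_scan_missing <- seq_len(n) <= n_missing
    out$liver_fat[out$liver_scan_missing] <- NA_real_
    out$pancreas_fat[out$liver_scan_missing] <- NA_real_
    out
  }

  strata <- list()
  with_seed(seed, {
    if (n_female > 0) strata$female <- draw_stratum(n_female, "female")
    if (n_male > 0) strata$male <- draw_stratum(n_male, "male")
  })
  out <- do.call(rbind, strata)
  if (is.null(out)) {
    out <- as.data.frame(setNames(
      lapply(.imio_cohort_cols, function(x) logical(0)), .imio_cohort_cols))
  } else {
    out$id <- sprintf("%s%04d", ifelse(out$sex == "female", "F", "M"),
                      unlist(lapply(strata, function(d) seq_len(nrow(d)))))
    out <- out[, .imio_cohort_cols]
  }
  rownames(out) <- NULL
  class(out) <- c("imio_cohort", "data.frame")
  out
}

#' @export
print.imio_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d female, %d male)\n",
              nrow(x), sum(x$sex == "female"), sum(x$sex == "male")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 4), digits = 3)
  invisible(x)
}

#' Table-1-style stratified summary of a cohort
#'
#' @param object an `imio_cohort`.
#' @param ... unused.
#' @return Data frame of per-sex N, mean and SD for every numeric variable
#'   (liver/pancreas fat restricted to subjects with a liver scan).
#' @export
summary.imio_cohort <- function(object, ...) {
  vars <- setdiff(.imio_cohort_cols, c("id", "sex", "liver_scan_missing"))
  rows <- lapply(vars, function(nm) {
    per_sex <- lapply(c("female", "male"), function(sx) {
      v <- object[[nm]][object$sex == sx]
      v <- v[!is.na(v)]
      c(n = length(v), mean = mean(v), sd = sd(v))
    })
    data.frame(variable = nm,
               n_female = per_sex[[1]]["n"], mean_female = per_sex[[1]]["mean"],
               sd_female = per_sex[[1]]["sd"],
               n_male = per_sex[[2]]["n"], mean_male = per_sex[[2]]["mean"],
               sd_male = per_sex[[2]]["sd"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a cohort table as CSV
#'
#' UTF-8, header row, '.' decimal separator.
#'
#' @param cohort an `imio_cohort`.
#' @param path file path.
#' @return `read_cohort` returns an `imio_cohort`; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(.imio_cohort_cols, names(out))
  if (length(missing_cols))
    stop("cohort file lacks columns: ", paste(missing_cols, collapse = ", "))
  class(out) <- c("imio_cohort", "data.frame")
  out
}
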