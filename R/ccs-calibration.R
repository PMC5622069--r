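## Travelling-wave ion mobility CCS calibration.
##
## Standard power-law calibration: corrected drift time
##   t' = t_d - edc * sqrt(m/z) / 1000        (EDC transport-delay correction)
## and reduced, charge-normalised literature cross section
##   CCS' = CCS_lit * sqrt(mu) / z,  mu = m * m_gas / (m + m_gas),
## fitted as ln(CCS') = ln(a) + b * ln(t') by ordinary least squares.

.reducedMass <- function(mass, gasMass) mass * gasMass / (mass + gasMass)

.correctedDriftTime <- function(driftTime, mass, z, edc) {
  mzv <- (mass + z * PROTON_MASS) / z
  driftTime - edc * sqrt(mzv) / 1000
}

#' Fit a power-law CCS calibration from calibrant ions
#'
#' @param calibrants data.frame with columns `name`, `mass` (Da), `z`,
#'   `drift_time` (ms) and `ccs_lit` (literature cross section, A^2, in the
#'   drift gas given by `gasMass`)
#' @param edcCoefficient instrument EDC delay coefficient
#' @param gasMass drift gas mass in Da (nitrogen by default)
#' @return a [CCSCalibration]
#' @examples
#' cal <- simulateCalibrants(log(250), 0.55, n = 8, seed = 1)
#' fitCalibration(cal)
#' @export
fitCalibration <- function(calibrants, edcCoefficient = 1.57,
                           gasMass = 28.0134) {
  need <- c("mass", "z", "drift_time", "ccs_lit")
  stopifnot(all(need %in% names(calibrants)))
  if (nrow(calibrants) < 2L || length(unique(calibrants$drift_time)) < 2L)
    qmStop("need at least 2 calibrants with distinct drift times",
           "qmInsufficientData")
  tprime <- .correctedDriftTime(calibrants$drift_time, calibrants$mass,
                                calibrants$z, edcCoefficient)
  bad <- which(tprime <= 0)
  if (length(bad)) {
    nm <- if ("name" %in% names(calibrants)) calibrants$name[bad[1]]
          else paste("row", bad[1])
    qmStop(sprintf("non-positive corrected drift time for calibrant %s", nm),
           "qmDomainError")
  }
  mu <- .reducedMass(calibrants$mass, gasMass)
  y <- log(calibrants$ccs_lit * sqrt(mu) / calibrants$z)
  x <- log(tprime)
  fit <- stats::lm(y ~ x)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (nrow(calibrants) == 2L || ssTot == 0) 1
        else max(0, min(1, 1 - sum(stats::residuals(fit)^2) / ssTot))
  CCSCalibration(lnA = unname(stats::coef(fit)[1]),
                 b = unname(stats::coef(fit)[2]),
                 edcCoefficient = edcCoefficient, gasMass = gasMass,
                 rSquared = r2)
}

#' Convert a drift time to a collision cross section
#'
#' Inverts the fitted calibration:
#' `CCS = exp(ln_a + b * ln(t')) * z / sqrt(mu)`.
#'
#' @param calibration a [CCSCalibration]
#' @param driftTime measured drift time (ms)
#' @param mass ion neutral mass (Da)
#' @param z charge state
#' @return cross section in A^2
#' @export
ccsOf <- function(calibration, driftTime, mass, z) {
  stopifnot(driftTime > 0, mass > 0, z >= 1)
  tprime <- .correctedDriftTime(driftTime, mass, z,
                                calibration@edcCoefficient)
  if (any(tprime <= 0))
    qmStop("non-positive corrected drift time", "qmDomainError")
  mu <- .reducedMass(mass, calibration@gasMass)
  exp(calibration@lnA + calibration@b * log(tprime)) * z / sqrt(mu)
}
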