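#' Translate log-hazard coefficients into years
#'
#' Under a Gompertz log-hazard `log h(t) = log h0 + Gamma t + beta n`,
#' one unit of a covariate shifts the hazard curve along the age axis by
#' `beta / Gamma` years: each additional ultra-rare PTV costs
#' `beta / Gamma` years of life (or healthspan).
#'
#' @param beta log-hazard per covariate unit (e.g. per mutation).
#' @param gamma per-year Gompertz slope, strictly positive.
#' @return years per covariate unit.
#' @export
years_per_unit <- function(beta, gamma) {
  if (any(gamma <= 0)) stop("Gompertz slope must be positive")
  beta / gamma
}

#' Mortality-rate doubling time
#'
#' `ln(2) / Gamma`, the time over which a Gompertz hazard doubles.
#'
#' @param gamma per-year Gompertz slope, strictly positive.
#' @return doubling time in years.
#' @export
doubling_time <- function(gamma) {
  if (any(gamma <= 0)) stop("Gompertz slope must be positive")
  log(2) / gamma
}

#' Burden variability expressed in years
#'
#' Scales the per-mutation effect by the population SD of the burden:
#' `sd * beta / gamma` years of life/healthspan variability attributable
#' to burden variation.
#'
#' @param sd standard deviation of the burden (mutations).
#' @inheritParams years_per_unit
#' @return years of variability.
#' @export
burden_sd_effect <- function(sd, beta, gamma) {
  if (any(sd < 0)) stop("SD must be non-negative")
  sd * years_per_unit(beta, gamma)
}

#' Parameters of the somatic PTV accumulation model
#'
#' @param beta log-hazard per mutation (default the lifespan estimate,
#'   0.046).
#' @param lambda fraction of the genome covered by ultra-rare PTV-capable
#'   sites; default `1e4 / 3e9` (10 kbp of a 3-Gbp genome).
#' @param L genome size in base pairs.
#' @param R somatic mutation rate per base pair per year.
#' @param gamma per-year Gompertz slope.
#' @return object of class `somatic_params`.
#' @export
somatic_params <- function(beta = 0.046, lambda = 1e4 / 3e9,
                           L = 3e9, R = 1e-8, gamma = 0.09) {
  stopifnot(beta > 0, lambda > 0, lambda <= 1, L > 0, R > 0, gamma > 0)
  structure(list(beta = beta, lambda = lambda, L = L, R = R,
                 gamma = gamma),
            class = "somatic_params")
}

#' Expected somatic ultra-rare PTV burden at a given age
#'
#' Somatic PTVs accumulate linearly with age at rate `lambda * L * R`
#' per year, so the expected burden at age `t` is `lambda * L * R * t`.
#'
#' @param params a [somatic_params()].
#' @param t age in years (vectorized), non-negative.
#' @return expected accumulated somatic ultra-rare PTVs.
#' @export
somatic_burden_at_age <- function(params, t) {
  stopifnot(inherits(params, "somatic_params"), all(t >= 0))
  params$lambda * params$L * params$R * t
}

#' Somatic contribution to the mortality log-hazard slope
#'
#' The somatic burden term contributes `beta * lambda * L * R` per year
#' to the log-hazard, to be compared with the Gompertz slope `Gamma`.
#' The contribution is judged negligible when the ratio falls below
#' `threshold`.
#'
#' @param params a [somatic_params()].
#' @param threshold ratio below which the somatic term is negligible.
#' @return list with `slope` (per year), `ratio` (slope / Gamma) and
#'   `verdict` (`"negligible"` or `"non-negligible"`).
#' @export
somatic_hazard_slope <- function(params, threshold = 1e-2) {
  stopifnot(inherits(params, "somatic_params"))
  slope <- params$beta * params$lambda * params$L * params$R
  ratio <- slope / params$gamma
  list(slope = slope, ratio = ratio,
       verdict = if (ratio < threshold) "negligible" else "non-negligible")
}
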