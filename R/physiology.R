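#' Thermal-time phenology parameters
#'
#' Physiological development time (PDT) accumulates daily effective
#' temperature above a base threshold, normalized so that one physiological
#' day equals one calendar day at the reference temperature:
#' `dPDT = max(0, T_mean - T_base) / pdt_norm` with
#' `pdt_norm = T_ref - T_base` by default.
#'
#' @param t_base base temperature, degC (default 8).
#' @param t_ref reference temperature, degC (default 25).
#' @param pdt_norm degC day per physiological day (default `t_ref - t_base`).
#' @return Object of class `phenology_params`.
#' @export
phenology_params <- function(t_base = 8, t_ref = 25,
                             pdt_norm = t_ref - t_base) {
  if (pdt_norm <= 0 || t_ref <= t_base)
    edfm_stop("edfm_invalid_argument", "need t_ref > t_base and pdt_norm > 0")
  structure(list(t_base = t_base, t_ref = t_ref, pdt_norm = pdt_norm),
            class = "phenology_params")
}

#' Daily physiological-day increment from mean temperature
#'
#' @param t_mean daily mean air temperature, degC.
#' @param params a [phenology_params()].
#' @return Non-negative increment in physiological days.
#' @export
pdt_increment <- function(t_mean, params = phenology_params()) {
  stopifnot(is.finite(t_mean))
  max(0, t_mean - params$t_base) / params$pdt_norm
}

#' Water-response parameters with root osmotic adjustment
#'
#' @param theta_wp wilting point, m3 m-3.
#' @param theta_fc field capacity, m3 m-3.
#' @param gamma shape exponent on relative available water (> 0; crop- and
#'   stage-dependent, default 1).
#' @param psi_root root osmotic adjustment coefficient (default -0.3).
#'   Nominally in MPa; it enters the stress factor as the dimensionless
#'   modifier `(1 + psi_root)` — see the package vignette for the unit
#'   tension this carries.
#' @return Object of class `water_params`.
#' @export
water_params <- function(theta_wp = 0.10, theta_fc = 0.32, gamma = 1,
                         psi_root = -0.3) {
  if (!(theta_wp > 0 && theta_wp < theta_fc))
    edfm_stop("edfm_invalid_argument", "need 0 < theta_wp < theta_fc")
  if (gamma <= 0)
    edfm_stop("edfm_invalid_argument", "gamma must be positive")
  if (1 + psi_root <= 0)
    edfm_stop("edfm_invalid_argument", "need 1 + psi_root > 0")
  structure(list(theta_wp = theta_wp, theta_fc = theta_fc, gamma = gamma,
                 psi_root = psi_root), class = "water_params")
}

#' Water stress factor with root osmotic adjustment
#'
#' `WSF = ((theta - theta_wp) / (theta_fc - theta_wp))^gamma * (1 + psi_root)`
#' with `theta` clamped into `[theta_wp, theta_fc]` first. Monotone
#' non-decreasing in `theta`, 0 at wilting point and `1 + psi_root` at field
#' capacity.
#'
#' @param theta soil volumetric water content, m3 m-3 (vectorized).
#' @param params a [water_params()].
#' @return WSF value(s) in `[0, 1 + psi_root]`.
#' @export
water_stress_factor <- function(theta, params = water_params()) {
  stopifnot(inherits(params, "water_params"))
  th <- pmin(params$theta_fc, pmax(params$theta_wp, theta))
  rel <- (th - params$theta_wp) / (params$theta_fc - params$theta_wp)
  rel^params$gamma * (1 + params$psi_root)
}

#' Daily assimilate supply from intercepted light
#'
#' A light-use-efficiency supply standing behind the photosynthesis
#' interface: `E = lue * I * min(1, Vcmax / Vcmax_ref) * WSF` (g CH2O per
#' plant per day). The `Vcmax` modifier is the hook through which the
#' previous day's light-capture feedback acts; a full biochemical
#' photosynthesis model can replace this function without touching the rest
#' of the loop.
#'
#' @param intercepted_par intercepted PAR, mol photons per plant per day.
#' @param mean_vcmax canopy mean Vcmax, umol m-2 s-1.
#' @param wsf water stress factor.
#' @param lue light-use efficiency, g CH2O per mol photons (default 0.8).
#' @param vcmax_ref reference Vcmax, umol m-2 s-1 (default 60).
#' @return Assimilate supply `E` (g CH2O per plant per day).
#' @export
daily_assimilation <- function(intercepted_par, mean_vcmax, wsf,
                               lue = 0.8, vcmax_ref = 60) {
  stopifnot(intercepted_par >= 0, mean_vcmax >= 0, wsf >= 0)
  lue * intercepted_par * min(1, mean_vcmax / vcmax_ref) * wsf
}

#' Sink-strength assimilate allocation
#'
#' Each organ receives `Q_organ = R_organ / sum(R) * E`; the last organ
#' absorbs the floating-point residual so the allocations sum to `E`
#' exactly (daily carbon conservation).
#'
#' @param E daily assimilate supply, g CH2O per plant.
#' @param R numeric vector of organ sink strengths (non-negative, at least
#'   one positive when `E > 0`).
#' @return Numeric vector `Q` of per-organ allocations, `sum(Q) == E`.
#' @export
allocate <- function(E, R) {
  stopifnot(E >= 0, all(R >= 0))
  sR <- sum(R)
  if (sR == 0) {
    if (E > 0)
      edfm_stop("edfm_allocation_error",
                "all sink strengths are zero but supply E = %g > 0", E)
    return(rep(0, length(R)))
  }
  Q <- R / sR * E
  if (length(Q) > 1) Q[length(Q)] <- E - sum(Q[-length(Q)])
  Q
}

#' Light-capture feedback on photosynthetic capacity
#'
#' `Vcmax_new = Vcmax_ref * clamp(ratio, 0.2, 1.5)^beta`: organs capturing
#' more light than the reference exposure up-regulate capacity, shaded
#' organs down-regulate it. At `ratio = 1` (or `beta = 0`) the reference
#' capacity is returned.
#'
#' @param light_capture_ratio captured / reference exposure (>= 0).
#' @param vcmax_ref reference Vcmax, umol m-2 s-1.
#' @param beta feedback exponent (default 0.5).
#' @return Updated Vcmax, umol m-2 s-1.
#' @export
update_vcmax <- function(light_capture_ratio, vcmax_ref = 60, beta = 0.5) {
  stopifnot(light_capture_ratio >= 0)
  vcmax_ref * (pmin(1.5, pmax(0.2, light_capture_ratio)))^beta
}
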