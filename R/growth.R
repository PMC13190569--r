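#' Logistic organ-growth parameters on physiological time
#'
#' @param Lmax asymptotic size (cm2 for leaf area, cm for internode length).
#' @param k growth rate per physiological day (default 0.15).
#' @param PDTm physiological day of the inflection (half of `Lmax`).
#' @return Object of class `growth_params`.
#' @export
growth_params <- function(Lmax, k = 0.15, PDTm) {
  if (Lmax <= 0 || k <= 0 || PDTm <= 0)
    edfm_stop("edfm_invalid_argument", "Lmax, k and PDTm must all be positive")
  structure(list(Lmax = Lmax, k = k, PDTm = PDTm), class = "growth_params")
}

#' Logistic organ size at a given physiological development time
#'
#' `L(PDT) = Lmax / (1 + exp(-k (PDT - PDTm)))`: strictly increasing in PDT,
#' bounded in `(0, Lmax)`, equal to `Lmax / 2` at the inflection `PDTm`.
#'
#' @param pdt physiological development time (vectorized).
#' @param params a [growth_params()].
#' @return Organ size(s) in the units of `Lmax`.
#' @export
logistic_size <- function(pdt, params) {
  stopifnot(inherits(params, "growth_params"))
  params$Lmax / (1 + exp(-params$k * (pdt - params$PDTm)))
}

#' Potential growth rate dL/dPDT of the logistic law
#'
#' Used as the organ's sink strength: demand peaks at the inflection and
#' vanishes before initiation and after maturity.
#'
#' @inheritParams logistic_size
#' @return Derivative value(s), size units per physiological day.
#' @export
logistic_rate <- function(pdt, params) {
  L <- logistic_size(pdt, params)
  params$k * L * (1 - L / params$Lmax)
}
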