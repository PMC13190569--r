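#' Prediction error and agreement metrics
#'
#' `rmse` is the root mean square error, `r_squared` the coefficient of
#' determination `1 - SS_res / SS_tot`, and `nrmse` the RMSE normalized by
#' the observation mean (range normalization available via `normalizer`).
#'
#' @param pred,obs numeric vectors of equal length.
#' @return Scalar metric value.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 1)
    edfm_stop("edfm_invalid_argument", "pred and obs must have equal length >= 1")
  sqrt(mean((pred - obs)^2))
}

#' @rdname rmse
#' @export
r_squared <- function(pred, obs) {
  if (length(pred) != length(obs))
    edfm_stop("edfm_invalid_argument", "length mismatch")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0)
    edfm_stop("edfm_undefined_metric", "R-squared undefined for constant obs")
  1 - sum((obs - pred)^2) / ss_tot
}

#' @rdname rmse
#' @param normalizer `"mean"` (default) or `"range"` of the observations.
#' @export
nrmse <- function(pred, obs, normalizer = c("mean", "range")) {
  normalizer <- match.arg(normalizer)
  denom <- if (normalizer == "mean") mean(obs) else diff(range(obs))
  if (denom == 0)
    edfm_stop("edfm_undefined_metric",
              "NRMSE undefined: zero %s of observations", normalizer)
  rmse(pred, obs) / denom
}

#' Percent reduction of an error metric versus a reference
#'
#' `100 * (reference - candidate) / reference`; positive when the candidate
#' improves on the reference.
#'
#' @param reference reference model's error (> 0).
#' @param candidate candidate model's error.
#' @return Percent reduction.
#' @export
percent_reduction <- function(reference, candidate) {
  if (reference <= 0)
    edfm_stop("edfm_invalid_argument", "reference error must be positive")
  100 * (reference - candidate) / reference
}

#' Load the packaged benchmark comparison table
#'
#' A transcription of published organ-parameter prediction errors for
#' WOFOST, GAMF, YOLO-DBM and the EDFM model (plant-height RMSE in mm, LAI
#' RMSE in percent, leaf length/width R-squared, peak attention weight).
#' Note: the published height RMSEs are reported in mm in the table and
#' once as cm in the accompanying prose; the fixture follows the table
#' (mm).
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return data.frame with one row per model.
#' @export
load_benchmark_table <- function(path = system.file("extdata",
                                                    "table6_benchmark.csv",
                                                    package = "edfm")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Percent reductions of the EDFM row versus every baseline
#'
#' For plant-height RMSE and LAI RMSE, computes the percent reduction of
#' the EDFM model relative to each baseline row, rounded to one decimal
#' place.
#'
#' @param table benchmark data.frame as from [load_benchmark_table()].
#' @return data.frame: `baseline`, `metric`, `reference`, `candidate`,
#'   `reduction_pct` (1 d.p.).
#' @export
comparison_report <- function(table = load_benchmark_table()) {
  need <- c("model", "height_rmse_mm", "lai_rmse_pct")
  if (!all(need %in% names(table)))
    edfm_stop("edfm_invalid_argument", "benchmark table missing columns")
  ed <- table[table$model == "EDFM", ]
  if (nrow(ed) != 1)
    edfm_stop("edfm_invalid_argument", "table must contain exactly one EDFM row")
  base <- table[table$model != "EDFM", ]
  if (nrow(base) == 0)
    return(data.frame(baseline = character(), metric = character(),
                      reference = numeric(), candidate = numeric(),
                      reduction_pct = numeric()))
  rows <- lapply(seq_len(nrow(base)), function(i) {
    data.frame(
      baseline = rep(base$model[i], 2),
      metric = c("height_rmse_mm", "lai_rmse_pct"),
      reference = c(base$height_rmse_mm[i], base$lai_rmse_pct[i]),
      candidate = c(ed$height_rmse_mm, ed$lai_rmse_pct),
      reduction_pct = round(c(
        percent_reduction(base$height_rmse_mm[i], ed$height_rmse_mm),
        percent_reduction(base$lai_rmse_pct[i], ed$lai_rmse_pct)), 1))
  })
  do.call(rbind, rows)
}

#' Fit the logistic growth law to an observed (PDT, size) series
#'
#' Nonlinear least squares for `(Lmax, k, PDTm)` with documented
#' initialization: `Lmax0 = 1.05 * max(L)`, `PDTm0` the PDT at half of
#' `Lmax0` (interpolated), `k0` the slope of the log-linearized interior
#' points `log(L / (Lmax0 - L)) ~ PDT`. Reports estimates, standard errors
#' and an identifiability warning when the data do not span the inflection
#' (all observations below half the fitted asymptote).
#'
#' @param pdt physiological development time of each observation.
#' @param L observed sizes.
#' @return List of class `logistic_fit`: `params` (a [growth_params()]),
#'   `se` (named standard errors), `rss`, `converged`, `warning` (NULL or
#'   text).
#' @export
fit_logistic_growth <- function(pdt, L) {
  if (length(pdt) != length(L) || length(L) < 5)
    edfm_stop("edfm_invalid_argument", "need >= 5 paired observations")
  Lmax0 <- 1.05 * max(L)
  half <- Lmax0 / 2
  above <- which(L >= half)
  PDTm0 <- if (length(above)) {
    i <- above[1]
    if (i == 1) pdt[1]
    else pdt[i - 1] + (half - L[i - 1]) / (L[i] - L[i - 1]) *
      (pdt[i] - pdt[i - 1])
  } else max(pdt)
  frac <- pmin(0.98, pmax(0.02, L / Lmax0))
  interior <- frac > 0.05 & frac < 0.95
  k0 <- if (sum(interior) >= 2) {
    sl <- stats::coef(stats::lm(log(frac / (1 - frac))[interior] ~
                                  pdt[interior]))[2]
    max(1e-3, unname(sl))
  } else 0.1
  fit <- tryCatch(
    minpack.lm::nlsLM(L ~ Lmax / (1 + exp(-k * (pdt - PDTm))),
                      start = list(Lmax = Lmax0, k = k0, PDTm = PDTm0),
                      lower = c(1e-8, 1e-8, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      edfm_stop("edfm_fit_error",
                "logistic fit failed (starts Lmax=%.3g k=%.3g PDTm=%.3g): %s",
                Lmax0, k0, PDTm0, conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  warn <- NULL
  if (max(L) < cf[["Lmax"]] / 2) {
    warn <- paste("observations never reach half the fitted asymptote;",
                  "Lmax is weakly identified (see its standard error)")
    warning(warn)
  }
  structure(list(
    params = growth_params(cf[["Lmax"]], cf[["k"]], cf[["PDTm"]]),
    se = stats::setNames(as.numeric(se), c("Lmax", "k", "PDTm")),
    rss = sum(stats::residuals(fit)^2),
    converged = TRUE, warning = warn
  ), class = "logistic_fit")
}
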