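#' Fit a capture-rate calibration curve
#'
#' Linear fit of event frequency (1/interval time) against molar
#' concentration. The slope is the capture constant k (events s^-1 per
#' mol L^-1) and the intercept the blank rate. Fitting on frequency
#' rather than interval keeps errors approximately Gaussian at high
#' counts; both views are equivalent for display.
#'
#' @param concentrations mol L^-1 (>= 3 values spanning >= 1 decade).
#' @param frequencies observed event frequencies, s^-1.
#' @param counts optional event counts behind each frequency (enables the
#'   blank-sigma LOD convention).
#' @param times optional observation times, s.
#' @param voltage,temperature condition metadata (mV, degrees C).
#' @return object of class `calibration_model`: `k`, `blank_rate`,
#'   `r_squared`, `linear_range`, `lod` (list with both conventions),
#'   `conditions`, and the `lm` fit.
#' @export
fit_calibration <- function(concentrations, frequencies, counts = NULL,
                            times = NULL, voltage = -50, temperature = 20) {
  stopifnot(length(concentrations) == length(frequencies))
  if (length(concentrations) < 3) stop("need >= 3 calibration points")
  if (max(concentrations) / max(min(concentrations), .Machine$double.xmin) < 10)
    stop("calibration points must span at least one decade")
  if (any(diff(frequencies[order(concentrations)]) <
          -0.5 * max(frequencies)))
    warning("grossly non-monotone calibration series; check the data")
  df <- data.frame(conc = concentrations, freq = frequencies)
  fit <- stats::lm(freq ~ conc, data = df)
  k <- unname(stats::coef(fit)[2])
  blank <- unname(stats::coef(fit)[1])
  if (k <= 0) warning("non-positive capture constant; calibration invalid")
  # LOD conventions: (a) lowest calibrated point (operational); (b) lowest
  # concentration whose rate exceeds blank + 3 * Poisson sigma of the blank
  lod_operational <- min(concentrations)
  lod_blank3s <- NA_real_
  if (!is.null(counts) && !is.null(times)) {
    blank_sigma <- sqrt(pmax(blank, 1e-12) / times)
    above <- frequencies > blank + 3 * blank_sigma
    if (any(above)) lod_blank3s <- min(concentrations[above])
  }
  structure(list(k = k, blank_rate = blank,
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 linear_range = range(concentrations),
                 lod = list(operational = lod_operational,
                            blank_3sigma = lod_blank3s),
                 conditions = list(voltage = voltage,
                                   temperature = temperature),
                 fit = fit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> k = %.4g /s/M, blank = %.3g /s, R^2 = %.4f, range [%.3g, %.3g] M\n",
    x$k, x$blank_rate, x$r_squared, x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' Estimate a concentration from an event frequency
#'
#' Inverts the calibration: `C = (f - blank) / k`, with a 95% confidence
#' interval propagated from Poisson counting error
#' (`sigma_f = sqrt(count) / time`). Zero observed events yields a
#' below-detection result with the Poisson zero-count upper bound
#' `~3 / (k T)` instead of a division crash.
#'
#' @param model a [fit_calibration()] model.
#' @param count events observed.
#' @param time observation time, s.
#' @return list: `concentration` (mol L^-1, NA when below detection),
#'   `ci` (length-2), `below_detection`, `upper_bound`.
#' @export
estimate_concentration <- function(model, count, time) {
  stopifnot(inherits(model, "calibration_model"), time > 0, count >= 0)
  if (count == 0) {
    return(list(concentration = NA_real_, ci = c(NA_real_, NA_real_),
                below_detection = TRUE,
                upper_bound = 3 / (model$k * time)))
  }
  f <- count / time
  conc <- (f - model$blank_rate) / model$k
  sd_f <- sqrt(count) / time
  ci <- (f + c(-1.96, 1.96) * sd_f - model$blank_rate) / model$k
  list(concentration = conc, ci = ci, below_detection = FALSE,
       upper_bound = ci[2])
}

#' Normalize mixture event counts to the smallest component
#'
#' Digital readout of a mixture: per-class signal counts divided by the
#' smallest positive count, so the least-abundant analyte maps to 1.
#'
#' @param counts named or unnamed numeric per-class counts (>= 1 must be
#'   positive).
#' @return numeric ratios, same names/order as `counts`.
#' @export
#' @examples
#' mixture_ratios(c(C2 = 100, C3 = 205, C4 = 297))
mixture_ratios <- function(counts) {
  if (all(counts == 0)) stop("all counts are zero")
  counts / min(counts[counts > 0])
}

#' Check rate additivity of a mixture
#'
#' In ideal dilute solution the overall capture rate of a mixture is the
#' sum of the partial rates `k_i C_i` of its components. Returns the
#' observed total rate, the predicted sum, and the z-score of their
#' difference under Poisson counting error; |z| > 3 indicates an
#' interaction (non-ideal mixture).
#'
#' @param total_count events observed for the mixture.
#' @param time observation time, s.
#' @param models named list of per-component [fit_calibration()] models.
#' @param concentrations named numeric of component concentrations,
#'   mol L^-1 (names must match `models`).
#' @return list: `observed_rate`, `predicted_rate`, `z`.
#' @export
additivity_check <- function(total_count, time, models, concentrations) {
  stopifnot(time > 0)
  comps <- names(concentrations)
  missing <- comps[!comps %in% names(models)]
  if (length(missing))
    stop("missing calibration for component(s): ",
         paste(missing, collapse = ", "))
  pred <- sum(vapply(comps, function(cp)
    models[[cp]]$k * concentrations[[cp]] + models[[cp]]$blank_rate,
    numeric(1)))
  obs <- total_count / time
  z <- (total_count - pred * time) / sqrt(pred * time)
  list(observed_rate = obs, predicted_rate = pred, z = z)
}

#' Convert a molar concentration to a mass concentration
#'
#' @param concentration mol L^-1.
#' @param formula elemental composition of the analyte (free acid), e.g.
#'   `"C2HF3O2"` for trifluoroacetic acid.
#' @return g L^-1.
#' @export
#' @examples
#' convert_molar_to_mass(1e-10, "C2HF3O2") * 1e9  # ~11.4 ng/L
convert_molar_to_mass <- function(concentration, formula) {
  stopifnot(all(concentration >= 0))
  concentration * molar_mass(formula)
}
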