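#' Fit the linear molecular-volume to current-blockade relationship
#'
#' Ordinary least squares of blockade (%) on conjugate volume (A^3),
#' optionally weighted by 1 / sigma^2 of each analyte's blockade
#' histogram. This line is the structure-signal model that lets the
#' blockade of an analyte never measured with a standard be predicted
#' from its MD-derived volume alone.
#'
#' @param volumes conjugate volumes, A^3 (>= 3 points).
#' @param blockades measured mean blockades, %.
#' @param sigmas optional per-point blockade standard deviations, %.
#' @param weighted if TRUE (and `sigmas` given) fit with weights
#'   1/sigma^2; default unweighted.
#' @param labels optional point labels.
#' @return object of class `volume_blockade_model`: `slope` (% A^-3),
#'   `intercept` (%), `r_squared`, `residual_sd` (%), `points`
#'   (data.frame), and the underlying `lm` fit.
#' @export
#' @examples
#' lib <- build_default_library(pfca_analytes(paste0("C", 2:9)))
#' m <- fit_volume_blockade(lib$volume, lib$blockade_mean)
#' m$slope  # ~0.023 % per cubic angstrom
fit_volume_blockade <- function(volumes, blockades, sigmas = NULL,
                                weighted = FALSE, labels = NULL) {
  stopifnot(length(volumes) == length(blockades))
  if (length(volumes) < 3) stop("need >= 3 (volume, blockade) points")
  w <- if (weighted) {
    if (is.null(sigmas)) stop("weighted fit needs sigmas")
    1 / sigmas^2
  } else NULL
  df <- data.frame(volume = volumes, blockade = blockades)
  fit <- if (is.null(w)) stats::lm(blockade ~ volume, data = df) else
    stats::lm(blockade ~ volume, data = df, weights = w)
  sm <- suppressWarnings(summary(fit))  # exact fits warn benignly
  pts <- data.frame(label = if (is.null(labels)) NA_character_ else labels,
                    volume = volumes, blockade = blockades,
                    sigma = if (is.null(sigmas)) NA_real_ else sigmas,
                    residual = stats::residuals(fit),
                    stringsAsFactors = FALSE)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 residual_sd = sm$sigma,
                 points = pts, fit = fit),
            class = "volume_blockade_model")
}

#' @export
print.volume_blockade_model <- function(x, ...) {
  cat(sprintf(
    "<volume_blockade_model> blockade%% = %.4f + %.6f * V(A^3), R^2 = %.5f, residual sd = %.4f%%\n",
    x$intercept, x$slope, x$r_squared, x$residual_sd))
  invisible(x)
}

#' Predict the blockade of an analyte from its molecular volume
#'
#' Standard-free signal prediction: point prediction `a + b V` with a
#' t-based prediction standard error (residual variance plus leverage).
#'
#' @param model a [fit_volume_blockade()] model.
#' @param volume conjugate volume(s), A^3 (> 0).
#' @param with_interval also return the prediction sigma?
#' @return data.frame `volume`, `blockade` and (if requested)
#'   `prediction_sd` (%).
#' @export
predict_blockade <- function(model, volume, with_interval = TRUE) {
  stopifnot(inherits(model, "volume_blockade_model"))
  if (any(volume <= 0)) stop("volume must be positive")
  nd <- data.frame(volume = volume)
  if (with_interval) {
    pr <- stats::predict(model$fit, newdata = nd, se.fit = TRUE)
    data.frame(volume = volume, blockade = unname(pr$fit),
               prediction_sd = sqrt(pr$se.fit^2 + pr$residual.scale^2))
  } else {
    data.frame(volume = volume,
               blockade = unname(stats::predict(model$fit, newdata = nd)))
  }
}

#' Derived physical quantities of the volume-blockade line
#'
#' The per-unit increment is the blockade gained per -CF2- unit
#' (`slope * unit_volume`); the effective transduction volume is the
#' volume at which the line extrapolates to 100% blockade,
#' `(100 - intercept) / slope`, reported in nm^3. For the built-in
#' library these evaluate to 1.68% per unit and 4.82 nm^3 — the inner
#' pore volume sensed between the constriction residues.
#'
#' @param model a [fit_volume_blockade()] model.
#' @param unit_volume volume of one -CF2- unit, A^3.
#' @return list: `increment_pct`, `effective_volume_nm3`.
#' @export
derived_quantities <- function(model, unit_volume = 73.5) {
  stopifnot(inherits(model, "volume_blockade_model"))
  if (model$slope <= 0) stop("non-physical fit: slope must be positive")
  list(increment_pct = model$slope * unit_volume,
       effective_volume_nm3 = (100 - model$intercept) / model$slope / 1000)
}

#' Candidate analytes for a measured blockade
#'
#' Blockade-window pre-assignment: returns every analyte whose predicted
#' blockade lies within the combined window
#' `n_sigma * (sigma_measured + sigma_predicted)` of the measurement.
#' An empty set means unassigned; a multi-label set is ambiguous (e.g.
#' the FTA/C5/C6 group) and is deferred to the multi-feature classifier.
#'
#' @param predictions data.frame with `label` and `blockade` columns
#'   (from [predict_blockade()] plus labels); an optional `sigma` column
#'   gives each analyte's blockade histogram spread (falling back to
#'   `prediction_sd`, then 0).
#' @param measured measured blockade, %.
#' @param sigma measurement blockade sigma, % (> 0).
#' @param n_sigma window half-width in combined sigma units (default 3:
#'   the sum of the three-sigma spreads of the measured and predicted
#'   analytes).
#' @return character vector of candidate labels (possibly empty).
#' @export
assign_by_blockade <- function(predictions, measured, sigma, n_sigma = 3) {
  stopifnot(is.data.frame(predictions), nrow(predictions) >= 1)
  if (sigma <= 0) stop("sigma must be positive")
  psd <- if ("sigma" %in% names(predictions)) predictions$sigma
  else if ("prediction_sd" %in% names(predictions))
    predictions$prediction_sd else 0
  window <- n_sigma * (sigma + psd)
  predictions$label[abs(predictions$blockade - measured) <= window]
}
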