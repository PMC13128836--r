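#' Canonical names of the 43-dimension feature vector
#'
#' Seven current-derived features (`blockade`, `isd`, `ipp`, `hpeak`,
#' `hfwhm`, `hskew`, `hkurt`) under each of the six conditioning settings,
#' plus the dwell time `tau_on` stored once: 6 x 7 + 1 = 43.
#'
#' @return character vector of length 43, in canonical order (`tau_on`
#'   first, then by condition then feature).
#' @export
feature_names <- function() {
  base <- c("blockade", "isd", "ipp", "hpeak", "hfwhm", "hskew", "hkurt")
  c("tau_on",
    as.vector(t(outer(feature_conditions(), base,
                      function(cn, f) paste0(f, "@", cn)))))
}

#' All-points-histogram statistics of within-event blockade values
#'
#' Computes the four histogram-shape features of the blockade scheme from
#' a vector of per-sample blockade values (%): the modal blockade
#' `H_peak`, the full width at half maximum `H_FWHM` (linearly
#' interpolated at half the modal bin count), sample skewness `H_skew`
#' and excess kurtosis `H_kurt` (Gaussian -> 0). Binning uses the
#' Freedman-Diaconis rule with a floor of 10 bins. A constant vector
#' returns `(value, 0, 0, 0)`.
#'
#' @param b numeric vector of blockade values (%), length >= 4.
#' @return named numeric: `hpeak`, `hfwhm`, `hskew`, `hkurt`.
#' @export
#' @examples
#' all_points_histogram_stats(rnorm(2000, 30, 1))  # hfwhm ~ 2.355
all_points_histogram_stats <- function(b) {
  if (length(b) < 4) stop("need >= 4 samples for histogram statistics")
  if (max(b) == min(b))
    return(c(hpeak = b[1], hfwhm = 0, hskew = 0, hkurt = 0))
  iqr <- stats::IQR(b)
  n <- length(b)
  bw <- if (iqr > 0) 2 * iqr / n^(1 / 3) else (max(b) - min(b)) / 10
  nbins <- max(10, ceiling((max(b) - min(b)) / bw))
  h <- graphics::hist(b, breaks = seq(min(b), max(b), length.out = nbins + 1),
                      plot = FALSE)
  cnt <- h$counts
  mid <- h$mids
  imax <- which.max(cnt)
  half <- cnt[imax] / 2
  # interpolated half-maximum crossings on both flanks of the modal bin
  left <- mid[1] - (mid[2] - mid[1]) / 2
  if (imax > 1) {
    for (i in imax:2) {
      if (cnt[i - 1] < half) {
        left <- mid[i - 1] + (half - cnt[i - 1]) / (cnt[i] - cnt[i - 1]) *
          (mid[i] - mid[i - 1])
        break
      }
    }
  }
  right <- mid[length(mid)] + (mid[2] - mid[1]) / 2
  if (imax < length(cnt)) {
    for (i in imax:(length(cnt) - 1)) {
      if (cnt[i + 1] < half) {
        right <- mid[i] + (cnt[i] - half) / (cnt[i] - cnt[i + 1]) *
          (mid[i + 1] - mid[i])
        break
      }
    }
  }
  m <- mean(b)
  s <- stats::sd(b)
  z <- (b - m) / s
  c(hpeak = mid[imax],
    hfwhm = max(right - left, 0),
    hskew = mean(z^3),
    hkurt = mean(z^4) - 3)
}

#' Extract the 43-dimension frequency-modulated feature vector of an event
#'
#' For each of the six conditioning settings (zero-phase low-pass at
#' 2000/800/500/200/100 Hz and wavelet denoising) the within-event samples
#' are converted to blockade units and seven features computed: the mean
#' blockade `ΔI/I0` (%), current standard deviation `I_sigma` (pA),
#' peak-to-peak `I_pp` (pA), and the four all-points-histogram statistics.
#' The dwell time `tau_on` (ms) is stored once — it is invariant to
#' conditioning by construction. Total: 43 entries.
#'
#' Conditioning is applied to the within-event samples in isolation (with
#' reflective padding), so the baseline-to-event step never enters the
#' filter and a noiseless rectangular event is reproduced exactly under
#' every condition.
#'
#' @param event one row of a [detect_events()] table (needs
#'   `start_index`, `end_index`, `dwell_ms`).
#' @param trace the `trace` the event came from.
#' @param i0 open-pore current, pA (from [estimate_baseline()]).
#' @param min_samples events with fewer within-event samples are flagged
#'   incomplete (returns NULL).
#' @return named numeric vector of length 43, or NULL for a too-short
#'   event.
#' @export
extract_event_features <- function(event, trace, i0 = NULL,
                                   min_samples = 4) {
  stopifnot(inherits(trace, "trace"))
  if (is.null(i0)) i0 <- estimate_baseline(trace)$i0
  a <- event$start_index + 1L
  b <- event$end_index
  if (b - a + 1L < min_samples) return(NULL)
  raw <- trace$samples[a:b]
  out <- numeric(0)
  for (cn in feature_conditions()) {
    seg <- condition_signal(raw, cn, trace$sampling_rate)
    blk <- (abs(i0) - abs(seg)) / abs(i0) * 100
    hs <- all_points_histogram_stats(blk)
    v <- c(mean(blk), stats::sd(seg), max(seg) - min(seg),
           hs[["hpeak"]], hs[["hfwhm"]], hs[["hskew"]], hs[["hkurt"]])
    names(v) <- paste0(c("blockade", "isd", "ipp", "hpeak", "hfwhm",
                         "hskew", "hkurt"), "@", cn)
    out <- c(out, v)
  }
  out <- c(tau_on = event$dwell_ms, out)
  out[feature_names()]
}

#' Condition a full trace under all six settings
#'
#' @param trace a `trace` object.
#' @return named list of conditioned sample vectors.
#' @export
condition_trace <- function(trace) {
  stats::setNames(lapply(feature_conditions(), function(cn)
    condition_signal(trace$samples, cn, trace$sampling_rate)),
    feature_conditions())
}

#' Feature table for all events of a trace
#'
#' Runs [extract_event_features()] over a detection table, dropping
#' incomplete (too short) events.
#'
#' @param events [detect_events()] output.
#' @param trace the source `trace`.
#' @param i0 optional open-pore current (pA).
#' @param batch batch identifier recorded per row.
#' @return data.frame: `event_id`, `batch`, 43 feature columns.
#' @export
extract_features <- function(events, trace, i0 = NULL, batch = "batch1") {
  if (is.null(i0)) i0 <- estimate_baseline(trace)$i0
  rows <- lapply(seq_len(nrow(events)), function(j)
    extract_event_features(events[j, ], trace, i0 = i0))
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) {
    out <- as.data.frame(matrix(numeric(0), 0, 43,
                                dimnames = list(NULL, feature_names())),
                         check.names = FALSE)
    return(cbind(data.frame(event_id = integer(), batch = character()), out))
  }
  m <- do.call(rbind, rows[keep])
  out <- as.data.frame(m, check.names = FALSE)
  cbind(data.frame(event_id = events$event_id[keep], batch = batch,
                   stringsAsFactors = FALSE), out)
}

#' Normalize a feature table by an internal standard
#'
#' Divides every feature column by the mean of that feature over the
#' internal standard's events, per recording batch (column `batch`, if
#' present), so the standard's mean maps to 1 and batch-to-batch gain
#' drifts cancel. By default all 43 features are normalized, including
#' `tau_on`; set `include_tau = FALSE` to normalize only current-derived
#' features.
#'
#' @param features data.frame with the 43 feature columns plus `label`
#'   (and optionally `batch`).
#' @param standard_label label of the internal standard (e.g. "C6", "C5"
#'   or "C3").
#' @param include_tau normalize `tau_on` too?
#' @return data.frame of the same shape, normalized.
#' @export
normalize_to_standard <- function(features, standard_label,
                                  include_tau = TRUE) {
  stopifnot("label" %in% names(features))
  cols <- intersect(feature_names(), names(features))
  if (!include_tau) cols <- setdiff(cols, "tau_on")
  batches <- if ("batch" %in% names(features)) features$batch else
    rep("batch1", nrow(features))
  out <- features
  for (bt in unique(batches)) {
    in_bt <- batches == bt
    std <- in_bt & features$label == standard_label
    if (!any(std))
      stop("internal standard '", standard_label, "' absent from batch '",
           bt, "'")
    for (cl in cols) {
      m <- mean(features[[cl]][std])
      if (m == 0) m <- 1   # degenerate feature; leave unscaled
      out[[cl]][in_bt] <- features[[cl]][in_bt] / m
    }
  }
  out
}
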