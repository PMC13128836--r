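#' Robust open-pore baseline estimate
#'
#' Estimates the open-pore current I0 and baseline noise sigma from a
#' trace that may contain blockade events. The estimator is the mode of an
#' all-points histogram (bin width sigma/4 from a robust MAD scale),
#' refined by the mean of the samples within +/- 2 sigma of the modal bin.
#' Blockades move current toward zero, away from the open-pore mode, so
#' the estimate is insensitive to events occupying up to about half the
#' recording.
#'
#' @param trace a [as_trace()] object or numeric vector of currents (pA).
#' @return list with `i0` (pA, signed) and `sigma` (pA).
#' @export
#' @examples
#' estimate_baseline(as_trace(rnorm(5000, -100, 2), 20000))
estimate_baseline <- function(trace) {
  x <- if (inherits(trace, "trace")) trace$samples else as.numeric(trace)
  if (length(x) == 0) stop("empty trace")
  s <- stats::mad(x)
  if (s == 0) {
    if (all(x == x[1])) {
      if (x[1] == 0) stop("degenerate all-zero trace: no baseline")
      return(list(i0 = x[1], sigma = 0))
    }
    s <- stats::sd(x)
  }
  if (s == 0 || !is.finite(s)) stop("degenerate trace: zero scale")
  bw <- s / 4
  breaks <- seq(min(x) - bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  # the open-pore level is the extreme (largest-|I|) strong mode: among
  # bins reaching at least 3/4 of the global maximum count, take the one
  # furthest from zero (blockades always sit between baseline and zero)
  cand <- which(h$counts >= 0.75 * max(h$counts))
  mode <- h$mids[cand[which.max(abs(h$mids[cand]))]]
  # refine twice with symmetric windows to undo the bin-center offset
  centre <- mean(x[abs(x - mode) <= 2 * s])
  centre <- mean(x[abs(x - centre) <= 2.5 * s])
  near <- x[abs(x - centre) <= 3 * s]
  i0 <- mean(near)
  sigma <- stats::sd(near)
  if (!is.finite(sigma)) sigma <- 0
  list(i0 = i0, sigma = sigma)
}

#' Detect blockade events in a trace
#'
#' Finds maximal runs of samples deviating from the baseline toward zero
#' by more than `threshold_sigma` baseline noise units, discards runs
#' shorter than `min_dwell_ms`, and measures per-event dwell time and
#' blockade. The reported blockade is computed on the 2000 Hz-conditioned
#' signal (the base conditioning of the feature scheme) as
#' `(|I0| - |mean in-event current|) / |I0| * 100`.
#'
#' @param trace a `trace` object.
#' @param threshold_sigma detection threshold in baseline-noise units.
#' @param min_dwell_ms minimum event duration, ms (clamped, with a
#'   warning, to two sampling periods).
#' @param baseline optional precomputed [estimate_baseline()] result.
#' @return data.frame with columns `event_id`, `start_index`, `end_index`
#'   (0-based, half-open), `start_s`, `dwell_ms`, `blockade_pct`,
#'   `blockade_raw_pct`, `mean_pa`.
#' @export
detect_events <- function(trace, threshold_sigma = 5, min_dwell_ms = 0.5,
                          baseline = NULL) {
  stopifnot(inherits(trace, "trace"))
  fs <- trace$sampling_rate
  if (is.null(baseline)) baseline <- estimate_baseline(trace)
  i0 <- baseline$i0
  sigma <- baseline$sigma
  min_samp <- 2
  min_req <- min_dwell_ms / 1000 * fs
  if (min_req < min_samp) {
    warning("min_dwell_ms below 2 sampling periods; clamping")
    min_req <- min_samp
  }
  x <- trace$samples
  # deviation toward zero: |x| below |i0| by more than the threshold
  dev <- abs(i0) - abs(x)
  excur <- dev > threshold_sigma * sigma
  if (!any(excur) || sigma == 0 && all(!excur)) {
    return(.empty_event_table())
  }
  r <- rle(excur)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_req
  if (!any(keep)) return(.empty_event_table())
  starts <- starts[keep]; ends <- ends[keep]
  out <- data.frame(
    event_id = seq_along(starts),
    start_index = starts - 1L,
    end_index = ends,                 # half-open [start, end)
    start_s = (starts - 1L) / fs,
    dwell_ms = (ends - starts + 1L) / fs * 1000,
    # blockade on the lp2000-conditioned within-event signal (base
    # condition of the feature scheme)
    blockade_pct = vapply(seq_along(starts), function(j) {
      seg <- condition_signal(x[starts[j]:ends[j]], "lp2000", fs)
      (abs(i0) - abs(mean(seg))) / abs(i0) * 100
    }, numeric(1)),
    blockade_raw_pct = vapply(seq_along(starts), function(j)
      (abs(i0) - abs(mean(x[starts[j]:ends[j]]))) / abs(i0) * 100,
      numeric(1)),
    mean_pa = vapply(seq_along(starts), function(j)
      mean(x[starts[j]:ends[j]]), numeric(1))
  )
  out
}

.empty_event_table <- function() {
  data.frame(event_id = integer(), start_index = integer(),
             end_index = integer(), start_s = numeric(),
             dwell_ms = numeric(), blockade_pct = numeric(),
             blockade_raw_pct = numeric(), mean_pa = numeric())
}

#' Per-label interval-time statistics
#'
#' Digital quantification primitive: for each label the event frequency is
#' `count / total_time` and the mean interval time is its reciprocal
#' `total_time / count` (robust to interleaving of labels in mixtures, and
#' asymptotically identical to the mean gap for Poisson streams). A label
#' with zero events gets frequency 0 and a censored interval equal to the
#' observation time.
#'
#' @param labels character/factor vector, one entry per detected event.
#' @param total_time total observation time, s.
#' @param all_labels optional label universe (so zero-count labels are
#'   reported).
#' @return data.frame `label`, `count`, `frequency_hz`,
#'   `mean_interval_s`, `censored`, `total_time_s`.
#' @export
#' @examples
#' interval_stats(rep("C2", 5), total_time = 10)
interval_stats <- function(labels, total_time, all_labels = NULL) {
  stopifnot(total_time > 0)
  labels <- as.character(labels)
  universe <- if (is.null(all_labels)) unique(labels) else
    union(all_labels, unique(labels))
  cnt <- vapply(universe, function(l) sum(labels == l), integer(1))
  data.frame(
    label = universe,
    count = cnt,
    frequency_hz = cnt / total_time,
    mean_interval_s = ifelse(cnt > 0, total_time / cnt, total_time),
    censored = cnt == 0,
    total_time_s = total_time,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
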