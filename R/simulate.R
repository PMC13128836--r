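#' Simulation configuration
#'
#' Assembles the configuration for a synthetic nanopore recording: global
#' acquisition settings plus a per-analyte parameter table (usually from
#' [build_default_library()]). Defaults mirror the wild-type aerolysin
#' recording conditions: 20 kHz sampling, -50 mV applied bias, -100 pA
#' open-pore current.
#'
#' @param analytes per-analyte parameter data.frame with columns `label`,
#'   `concentration`, `capture_constant`, `blockade_mean`, `blockade_sd`,
#'   `dwell_log_mean`, `dwell_log_sd`.
#' @param duration recording length, s.
#' @param sampling_rate Hz.
#' @param voltage applied bias, mV (negative).
#' @param open_pore_current pA (signed; negative at negative bias).
#' @param baseline_noise_sd baseline current noise, pA.
#' @param within_event_noise_mult multiplier on `baseline_noise_sd` inside
#'   events.
#' @param internal_standard optional list(label=, concentration=) spiked on
#'   top of `analytes`; the label must already be in the analyte table (its
#'   concentration is overridden).
#' @param seed integer RNG seed.
#' @return object of class `sim_config` (a list).
#' @export
sim_config <- function(analytes,
                       duration = 10,
                       sampling_rate = 20000,
                       voltage = -50,
                       open_pore_current = -100,
                       baseline_noise_sd = 2,
                       within_event_noise_mult = 1,
                       internal_standard = NULL,
                       seed = 1L) {
  stopifnot(duration > 0, sampling_rate > 0)
  stopifnot(is.data.frame(analytes),
            all(c("label", "concentration", "capture_constant",
                  "blockade_mean", "blockade_sd",
                  "dwell_log_mean", "dwell_log_sd") %in% names(analytes)))
  if (any(analytes$concentration < 0)) stop("concentrations must be >= 0")
  if (any(analytes$blockade_mean <= 0 | analytes$blockade_mean >= 100))
    stop("blockade means must lie in (0, 100)%")
  if (anyDuplicated(analytes$label)) stop("duplicate analyte labels")
  if (!is.null(internal_standard)) {
    i <- match(internal_standard$label, analytes$label)
    if (is.na(i)) stop("internal standard '", internal_standard$label,
                       "' not in analyte table")
    analytes$concentration[i] <- internal_standard$concentration
  }
  structure(list(analytes = analytes, duration = duration,
                 sampling_rate = sampling_rate, voltage = voltage,
                 open_pore_current = open_pore_current,
                 baseline_noise_sd = baseline_noise_sd,
                 within_event_noise_mult = within_event_noise_mult,
                 internal_standard = internal_standard,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Voltage dependence of the probe-determined capture constant
#'
#' Scales a reference capture constant to another applied bias with a
#' shared exponential law `k(V) = k0 * exp(-(V - V_ref) / V_s)` (V in mV,
#' more negative bias captures faster). The probe, not the analyte, sets
#' the capture kinetics, so the same law applies to every conjugate.
#'
#' @param k0 capture constant at `v_ref` (events s^-1 M^-1).
#' @param voltage target bias, mV.
#' @param v_ref reference bias, mV.
#' @param v_scale e-folding scale, mV.
#' @return scaled capture constant.
#' @export
capture_constant_at <- function(k0, voltage, v_ref = -50, v_scale = 20) {
  k0 * exp(-(voltage - v_ref) / v_scale)
}

#' Simulate a nanopore current trace
#'
#' Generates a synthetic ionic-current recording: Gaussian baseline noise
#' around the open-pore current, with rectangular blockade excursions
#' toward zero. Per-analyte arrivals are homogeneous Poisson processes with
#' rate `capture_constant * concentration`; dwell times are log-normal;
#' per-event blockade depths are Gaussian. Events are placed sequentially
#' from the merged arrival stream and an arrival that would overlap the
#' previous event is rejected (single-channel recordings essentially never
#' overlap); if more than half the arrivals are rejected the density is
#' unphysical and an error is raised.
#'
#' @param config a [sim_config()].
#' @return list with elements `trace` (a `trace` object, see
#'   [as_trace()]) and `truth` (data.frame `label`, `start_s`, `dwell_ms`,
#'   `blockade_pct` of the events actually placed).
#' @export
#' @examples
#' lib <- build_default_library(pfca_analytes(c("C2", "C4")), 2e-6)
#' sim <- simulate_trace(sim_config(lib, duration = 2, seed = 7))
#' nrow(sim$truth)
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  i0 <- config$open_pore_current
  rates <- config$analytes$capture_constant * config$analytes$concentration
  total_rate <- sum(rates)

  current <- stats::rnorm(n, mean = i0, sd = config$baseline_noise_sd)

  truth <- data.frame(label = character(), start_s = numeric(),
                      dwell_ms = numeric(), blockade_pct = numeric(),
                      stringsAsFactors = FALSE)
  if (total_rate > 0) {
    # merged Poisson stream: exponential gaps, analyte by rate share
    t_arr <- cumsum(stats::rexp(max(10, ceiling(total_rate * config$duration * 2)),
                                rate = total_rate))
    while (length(t_arr) && t_arr[length(t_arr)] < config$duration)
      t_arr <- c(t_arr, t_arr[length(t_arr)] +
                   cumsum(stats::rexp(10, rate = total_rate)))
    t_arr <- t_arr[t_arr < config$duration]
    n_arr <- length(t_arr)
    if (n_arr > 0) {
      which_a <- sample.int(nrow(config$analytes), n_arr, replace = TRUE,
                            prob = rates / total_rate)
      dwell_ms <- stats::rlnorm(n_arr,
                                config$analytes$dwell_log_mean[which_a],
                                config$analytes$dwell_log_sd[which_a])
      depth <- stats::rnorm(n_arr,
                            config$analytes$blockade_mean[which_a],
                            config$analytes$blockade_sd[which_a])
      depth <- pmin(pmax(depth, 0.1), 99.9)
      keep <- logical(n_arr)
      rejected <- 0L
      prev_end <- -Inf
      for (j in seq_len(n_arr)) {
        end_j <- t_arr[j] + dwell_ms[j] / 1000
        if (t_arr[j] <= prev_end) {
          rejected <- rejected + 1L
        } else if (end_j >= config$duration) {
          # would run past the recording; drop silently
        } else {
          keep[j] <- TRUE
          prev_end <- end_j
        }
      }
      if (n_arr > 0 && rejected / n_arr > 0.5)
        stop("more than 50% of arrivals overlap existing events; ",
             "use a shorter dwell, lower rates or a longer duration")
      if (any(keep)) {
        isd_scale <- if (is.null(config$analytes$isd_scale))
          rep(1, nrow(config$analytes)) else config$analytes$isd_scale
        for (j in which(keep)) {
          a <- round(t_arr[j] * fs) + 1L
          b <- min(n, a + max(1L, round(dwell_ms[j] / 1000 * fs)) - 1L)
          lev <- i0 * (1 - depth[j] / 100)
          sd_in <- config$baseline_noise_sd * config$within_event_noise_mult *
            isd_scale[which_a[j]]
          current[a:b] <- stats::rnorm(b - a + 1L, mean = lev, sd = sd_in)
        }
        truth <- data.frame(label = config$analytes$label[which_a[keep]],
                            start_s = t_arr[keep],
                            dwell_ms = dwell_ms[keep],
                            blockade_pct = depth[keep],
                            stringsAsFactors = FALSE)
      }
    }
  }
  trace <- as_trace(current, sampling_rate = fs, voltage = config$voltage,
                    metadata = list(open_pore_current = i0,
                                    electrolyte = "4 M KCl",
                                    pore = "WT AeL"))
  list(trace = trace, truth = truth)
}

#' Simulate a multiplexed mixture counting study
#'
#' Draws per-replicate event counts for a mixture of analytes with molar
#' concentrations proportional to `ratios` and identical per-molecule
#' capture constants (the probe-directed universality assumption). Arrivals
#' are independent Poisson processes, so conditional on the total each
#' replicate's class counts are multinomial with probabilities proportional
#' to the ratios.
#'
#' @param ratios positive molar ratios, e.g. `c(1, 2, 3)`.
#' @param n_events target expected total number of events per replicate.
#' @param seed integer seed.
#' @param replicates number of replicate runs.
#' @param labels optional component labels.
#' @return matrix of counts, `replicates` rows x `length(ratios)` columns.
#' @export
#' @examples
#' cnt <- simulate_mixture_study(c(1, 2, 3), n_events = 1500, seed = 1)
#' sweep(cnt, 1, apply(cnt, 1, min), "/")   # ~ (1, 2, 3)
simulate_mixture_study <- function(ratios, n_events = 1000, seed = 1L,
                                   replicates = 3L, labels = NULL) {
  if (length(ratios) == 0) stop("empty ratio list")
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (n_events < 1) stop("n_events must be >= 1")
  set.seed(seed)
  lam <- n_events * ratios / sum(ratios)
  counts <- t(vapply(seq_len(replicates),
                     function(i) stats::rpois(length(lam), lam),
                     numeric(length(lam))))
  colnames(counts) <- if (is.null(labels)) paste0("component", seq_along(ratios)) else labels
  counts
}

# Deterministic Monte Carlo of the extractor's own noise response:
# unit-variance white-noise segments of n samples are pushed through
# condition_signal and the per-condition feature statistics recorded.
# Cached per (condition, n, fs); RNG state is saved and restored.
.noise_stats_cache <- new.env(parent = emptyenv())

.noise_feature_stats <- function(condition, n, sampling_rate, nrep = 150) {
  key <- paste(condition, n, sampling_rate, sep = ":")
  hit <- .noise_stats_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(20260L)
  m <- matrix(NA_real_, nrep, 7,
              dimnames = list(NULL, c("mean", "isd", "ipp", "hpeak",
                                      "hfwhm", "hskew", "hkurt")))
  for (r in seq_len(nrep)) {
    y <- condition_signal(stats::rnorm(n), condition, sampling_rate)
    hs <- all_points_histogram_stats(y)
    m[r, ] <- c(mean(y), stats::sd(y), max(y) - min(y),
                hs[["hpeak"]], hs[["hfwhm"]], hs[["hskew"]], hs[["hkurt"]])
  }
  out <- list(mean = colMeans(m), sd = apply(m, 2, stats::sd))
  .noise_stats_cache[[key]] <- out
  out
}

#' Gaussian feature library for direct feature-space simulation
#'
#' Builds per-analyte Gaussian parameters (mean, sd) for each of the 43
#' frequency-modulated features. Blockade-type features take the
#' analyte's blockade mean with its histogram spread; the noise-derived
#' features (I_sigma, I_pp, histogram width and shape) are calibrated by
#' a deterministic Monte Carlo of the package's own conditioning
#' operator acting on white-noise segments of the analyte's typical
#' dwell length, so the library matches what [extract_event_features()]
#' actually produces; dwell time uses the log-normal moments.
#'
#' @param library per-analyte parameter table from
#'   [build_default_library()]; an optional `isd_scale` column scales the
#'   within-event current-noise features per analyte.
#' @param open_pore_current pA; sets the pA-to-percent conversion.
#' @param baseline_noise_sd within-event current noise, pA.
#' @param sampling_rate Hz.
#' @return object of class `feature_library`: list with `labels`,
#'   `features` (character 43), `mean` and `sd` (matrices, analyte x
#'   feature), and `provenance`.
#' @export
default_feature_library <- function(library,
                                    open_pore_current = -100,
                                    baseline_noise_sd = 2,
                                    sampling_rate = 20000) {
  stopifnot(is.data.frame(library), nrow(library) >= 1)
  feats <- feature_names()
  conds <- feature_conditions()
  isd_scale <- if (is.null(library$isd_scale)) rep(1, nrow(library)) else library$isd_scale
  i0 <- abs(open_pore_current)
  pctA <- 100 / i0  # pA of noise expressed in blockade percent
  mu <- sd <- matrix(NA_real_, nrow(library), length(feats),
                     dimnames = list(library$label, feats))
  for (a in seq_len(nrow(library))) {
    tau_mean <- exp(library$dwell_log_mean[a] + library$dwell_log_sd[a]^2 / 2)
    tau_sd <- tau_mean * sqrt(exp(library$dwell_log_sd[a]^2) - 1)
    mu[a, "tau_on"] <- tau_mean
    sd[a, "tau_on"] <- tau_sd
    n_typ <- max(8L, round(exp(library$dwell_log_mean[a]) / 1000 * sampling_rate))
    s_in <- baseline_noise_sd * isd_scale[a]   # pA, white at fs
    for (cn in conds) {
      ns <- .noise_feature_stats(cn, n_typ, sampling_rate)
      blk_m <- library$blockade_mean[a]
      blk_sd <- library$blockade_sd[a]
      # event-mean noise adds to the event-to-event blockade spread
      mu[a, paste0("blockade@", cn)] <- blk_m
      sd[a, paste0("blockade@", cn)] <- sqrt(blk_sd^2 +
                                               (ns$sd[["mean"]] * s_in * pctA)^2)
      mu[a, paste0("isd@", cn)] <- ns$mean[["isd"]] * s_in
      sd[a, paste0("isd@", cn)] <- max(ns$sd[["isd"]] * s_in, 1e-4)
      mu[a, paste0("ipp@", cn)] <- ns$mean[["ipp"]] * s_in
      sd[a, paste0("ipp@", cn)] <- max(ns$sd[["ipp"]] * s_in, 1e-4)
      mu[a, paste0("hpeak@", cn)] <- blk_m
      sd[a, paste0("hpeak@", cn)] <- sqrt(blk_sd^2 +
                                            (ns$sd[["hpeak"]] * s_in * pctA)^2)
      mu[a, paste0("hfwhm@", cn)] <- ns$mean[["hfwhm"]] * s_in * pctA
      sd[a, paste0("hfwhm@", cn)] <- max(ns$sd[["hfwhm"]] * s_in * pctA, 1e-4)
      mu[a, paste0("hskew@", cn)] <- -ns$mean[["hskew"]]  # blockade = -current
      sd[a, paste0("hskew@", cn)] <- max(ns$sd[["hskew"]], 1e-3)
      mu[a, paste0("hkurt@", cn)] <- ns$mean[["hkurt"]]
      sd[a, paste0("hkurt@", cn)] <- max(ns$sd[["hkurt"]], 1e-3)
    }
  }
  structure(list(labels = library$label, features = feats,
                 mean = mu, sd = sd, provenance = "simulated"),
            class = "feature_library")
}

#' Sample a labeled feature table from a Gaussian feature library
#'
#' Draws i.i.d. Gaussian rows per class in the 43-dimension feature space.
#' This is the direct feature-space shortcut used for classifier
#' experiments at realistic sample sizes (e.g. 2400 events per analyte,
#' split 2000 training / 400 test) without paying for full signal-level
#' simulation.
#'
#' @param flib a [default_feature_library()] object.
#' @param n_per_class events per analyte (may be 0: schema-only table).
#' @param seed integer seed.
#' @return data.frame with the 43 feature columns plus a `label` factor.
#' @export
simulate_feature_table <- function(flib, n_per_class, seed = 1L) {
  stopifnot(inherits(flib, "feature_library"))
  if (n_per_class < 0) stop("n_per_class must be >= 0")
  set.seed(seed)
  feats <- flib$features
  if (n_per_class == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(feats),
                                dimnames = list(NULL, feats)),
                         check.names = FALSE)
    out$label <- factor(character(), levels = flib$labels)
    return(out)
  }
  blocks <- lapply(seq_along(flib$labels), function(a) {
    m <- matrix(stats::rnorm(n_per_class * length(feats),
                             mean = rep(flib$mean[a, ], each = n_per_class),
                             sd = rep(flib$sd[a, ], each = n_per_class)),
                nrow = n_per_class)
    colnames(m) <- feats
    m
  })
  out <- as.data.frame(do.call(rbind, blocks), check.names = FALSE)
  out$label <- factor(rep(flib$labels, each = n_per_class),
                      levels = flib$labels)
  # physical floors: spreads and durations cannot be negative
  nonneg <- grep("^(isd|ipp|hfwhm)@|^tau_on$", feats, value = TRUE)
  for (f in nonneg) out[[f]] <- pmax(out[[f]], 1e-6)
  out
}
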