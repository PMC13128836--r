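#' Build an in-house feature library
#'
#' Constructs the per-analyte Gaussian feature parameters used for
#' classification and unknown-flagging. Blockade-type feature means come
#' from the volume-blockade model (standard-free prediction); the
#' remaining feature parameters come either from Gaussian fits (sample
#' mean/sd) to a measured or simulated feature table, or from the default
#' noise model when no data exist for an analyte. Provenance is recorded
#' per analyte.
#'
#' @param vmodel a [fit_volume_blockade()] model.
#' @param analytes analyte parameter table (needs `label`, `volume`,
#'   `blockade_sd`, `dwell_log_mean`, `dwell_log_sd`).
#' @param feature_table optional data.frame with 43 feature columns plus
#'   `label`; analytes present in it get moment-fitted parameters.
#' @param ... passed to [default_feature_library()] (noise model
#'   settings).
#' @return a `feature_library` with per-analyte `provenance`
#'   ("predicted" or "fitted").
#' @export
build_feature_library <- function(vmodel, analytes, feature_table = NULL,
                                  ...) {
  stopifnot(inherits(vmodel, "volume_blockade_model"))
  if (is.null(analytes$volume))
    stop("analytes need a 'volume' column for blockade prediction")
  params <- analytes
  pred <- predict_blockade(vmodel, analytes$volume)
  params$blockade_mean <- pred$blockade
  flib <- default_feature_library(params, ...)
  prov <- rep("predicted", length(flib$labels))
  if (!is.null(feature_table)) {
    for (a in seq_along(flib$labels)) {
      rows <- feature_table$label == flib$labels[a]
      if (sum(rows) >= 4) {
        for (f in flib$features) {
          flib$mean[a, f] <- mean(feature_table[[f]][rows])
          flib$sd[a, f] <- max(stats::sd(feature_table[[f]][rows]), 1e-9)
        }
        prov[a] <- "fitted"
      }
    }
  }
  flib$provenance <- stats::setNames(prov, flib$labels)
  flib
}

#' End-to-end run configuration
#'
#' @param sim a [sim_config()] describing the recording (or the one used
#'   to simulate it).
#' @param threshold_sigma,min_dwell_ms detection parameters.
#' @param classifier_train_n training events per class for the in-house
#'   classifier.
#' @param classifier a [bag_config()].
#' @param unknown_sigma flagging threshold for out-of-library events.
#' @param unknown_features features used for the out-of-library distance.
#'   The default is the base-condition set plus dwell: these are robust
#'   to event-to-event dwell variation, whereas the low-cutoff noise
#'   features depend strongly on event length.
#' @param anchor_labels analytes whose blockade means anchor the
#'   volume-blockade fit (default: all with >= 3 available).
#' @param seed global seed; per-stage seeds are derived from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim, threshold_sigma = 5, min_dwell_ms = 0.5,
                       classifier_train_n = 150,
                       classifier = bag_config(ntree = 50, folds = 5),
                       unknown_sigma = 3,
                       unknown_features = c("tau_on", "blockade@lp2000",
                                            "isd@lp2000", "ipp@lp2000",
                                            "hpeak@lp2000",
                                            "hfwhm@lp2000"),
                       anchor_labels = NULL, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, threshold_sigma = threshold_sigma,
                 min_dwell_ms = min_dwell_ms,
                 classifier_train_n = classifier_train_n,
                 classifier = classifier, unknown_sigma = unknown_sigma,
                 unknown_features = unknown_features,
                 anchor_labels = anchor_labels, seed = as.integer(seed)),
            class = "run_config")
}

# deterministic per-stage seed derivation, kept well below 2^31
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + stage * 7919L) %% 2000000011L
}

#' Run the standard-free sensing pipeline end to end
#'
#' Simulate (or ingest) a trace, detect events, extract the 43-dimension
#' features, identify each event (blockade-window pre-assignment for
#' unambiguous events, multi-feature bagged-tree classification for
#' ambiguous ones, out-of-library flagging last), count per-analyte
#' signals, and quantify concentrations from interval times. When the
#' configuration declares an internal standard, its observed event
#' frequency and known concentration recalibrate the universal capture
#' constant at run time; otherwise the configured capture constants are
#' used. Deterministic under the config seed.
#'
#' @param config a [run_config()].
#' @param trace optional pre-recorded `trace` (skips simulation; ground
#'   truth then unavailable).
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(config, trace = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  truth <- NULL
  if (is.null(trace)) {
    sim$seed <- .stage_seed(config$seed, 1L)
    simres <- simulate_trace(sim)
    trace <- simres$trace
    truth <- simres$truth
  }
  duration <- length(trace$samples) / trace$sampling_rate

  baseline <- estimate_baseline(trace)
  events <- detect_events(trace, threshold_sigma = config$threshold_sigma,
                          min_dwell_ms = config$min_dwell_ms,
                          baseline = baseline)
  feats <- extract_features(events, trace, i0 = baseline$i0)

  # standard-free identification machinery: volume-blockade line from the
  # anchor analytes, predicted blockades + classifier for the full library
  lib <- sim$analytes
  anchors <- if (is.null(config$anchor_labels)) lib$label else
    config$anchor_labels
  ai <- match(anchors, lib$label)
  if (length(ai) >= 3) {
    vmodel <- fit_volume_blockade(lib$volume[ai], lib$blockade_mean[ai],
                                  labels = lib$label[ai])
    flib <- build_feature_library(vmodel, lib,
                                  open_pore_current = baseline$i0,
                                  baseline_noise_sd = baseline$sigma,
                                  sampling_rate = trace$sampling_rate)
  } else {
    # too few anchors for a volume fit: use the configured blockade
    # means directly (internal-standard style library)
    vmodel <- NULL
    flib <- default_feature_library(lib,
                                    open_pore_current = baseline$i0,
                                    baseline_noise_sd = baseline$sigma,
                                    sampling_rate = trace$sampling_rate)
  }
  train <- simulate_feature_table(flib, config$classifier_train_n,
                                  seed = .stage_seed(config$seed, 2L))
  cls_cfg <- config$classifier
  cls_cfg$seed <- .stage_seed(config$seed, 3L)
  model <- train_bagged_trees(train[, feature_names()], train$label,
                              config = cls_cfg)

  pred_tab <- if (is.null(vmodel))
    data.frame(volume = lib$volume, blockade = lib$blockade_mean)
  else predict_blockade(vmodel, lib$volume)
  pred_tab$label <- lib$label
  pred_tab$sigma <- lib$blockade_sd
  sigma_meas <- mean(lib$blockade_sd)

  n_ev <- nrow(feats)
  assigned <- character(n_ev)
  method <- character(n_ev)
  if (n_ev > 0) {
    cand <- lapply(feats[["blockade@lp2000"]], function(b)
      assign_by_blockade(pred_tab, b, sigma = sigma_meas))
    x <- .as_feature_matrix(feats)[, model$features, drop = FALSE]
    cls_pred <- as.character(stats::predict(model$forest, x))
    for (j in seq_len(n_ev)) {
      if (length(cand[[j]]) == 1) {
        assigned[j] <- cand[[j]]
        method[j] <- "blockade-window"
      } else if (length(cand[[j]]) == 0) {
        assigned[j] <- NA_character_
        method[j] <- "unassigned"
      } else {
        assigned[j] <- cls_pred[j]
        method[j] <- "classifier"
      }
    }
    unknown <- flag_unknown_signals(feats, flib,
                                    threshold_sigma = config$unknown_sigma,
                                    feature_subset = config$unknown_features)
    assigned[unknown] <- NA_character_
    method[unknown] <- "flagged-unknown"
  } else {
    unknown <- logical(0)
  }

  counted <- assigned[!is.na(assigned)]
  istats <- interval_stats(counted, total_time = duration,
                           all_labels = lib$label)

  # capture constant: recalibrated from the internal standard if declared
  k_used <- lib$capture_constant
  names(k_used) <- lib$label
  if (!is.null(sim$internal_standard)) {
    std <- sim$internal_standard
    f_std <- istats$frequency_hz[istats$label == std$label]
    if (length(f_std) == 1 && f_std > 0 && std$concentration > 0)
      k_used[] <- f_std / std$concentration
  }
  conc <- data.frame(label = istats$label, count = istats$count,
                     frequency_hz = istats$frequency_hz,
                     concentration = istats$frequency_hz / k_used[istats$label],
                     stringsAsFactors = FALSE)
  # Poisson 95% CI on the count
  conc$ci_lo <- (conc$count - 1.96 * sqrt(pmax(conc$count, 1))) /
    duration / k_used[conc$label]
  conc$ci_hi <- (conc$count + 1.96 * sqrt(pmax(conc$count, 1))) /
    duration / k_used[conc$label]

  structure(list(
    baseline = baseline, events = events, features = feats,
    identification = if (n_ev > 0)
      data.frame(event_id = feats$event_id, label = assigned,
                 method = method, stringsAsFactors = FALSE)
    else data.frame(event_id = integer(), label = character(),
                    method = character()),
    interval_stats = istats, concentrations = conc,
    volume_model = vmodel, classifier = model, feature_library = flib,
    truth = truth,
    diagnostics = list(seed = config$seed, duration_s = duration,
                       n_events = n_ev, n_flagged = sum(unknown),
                       threshold_sigma = config$threshold_sigma,
                       min_dwell_ms = config$min_dwell_ms)),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<pipeline_report> %.3g s trace, baseline %.2f pA (sigma %.2f), %d events (%d flagged unknown)\n",
              d$duration_s, x$baseline$i0, x$baseline$sigma, d$n_events,
              d$n_flagged))
  cat("per-analyte quantification:\n")
  print(x$concentrations, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Serialize / restore a pipeline report or model
#'
#' Self-describing binary container (RDS) holding the object plus its
#' configuration and seed; [io_round_trip()] checks write-then-read
#' equality for any artifact and path.
#'
#' @param object any package artifact.
#' @param path file path.
#' @rdname artifact_io
#' @export
write_artifact <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_artifact <- function(path) readRDS(path)

#' @param writer,reader functions for a specific format (default binary
#'   artifact container).
#' @rdname artifact_io
#' @return `io_round_trip` returns TRUE invisibly or errors describing
#'   the mismatch.
#' @export
io_round_trip <- function(object, path = tempfile(),
                          writer = write_artifact, reader = read_artifact) {
  writer(object, path)
  back <- reader(path)
  if (!isTRUE(all.equal(object, back, tolerance = 1e-12)))
    stop("round trip altered the artifact: ",
         paste(all.equal(object, back), collapse = "; "))
  invisible(TRUE)
}
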