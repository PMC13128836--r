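# shared fixture builders (everything generated in code; no data files)

# small well-separated three-analyte library at a given molar concentration
tiny_library <- function(conc = 3e-6, labels = c("C2", "C5", "C9")) {
  build_default_library(pfca_analytes(labels), concentration = conc)
}

# trace with hand-placed rectangular pulses on a flat or noisy baseline
pulse_trace <- function(n_pulses = 10, depth_pct = 30, dwell_samples = 60,
                        gap_samples = 400, i0 = -100, noise_sd = 0,
                        fs = 20000, seed = 1) {
  set.seed(seed)
  n <- n_pulses * (dwell_samples + gap_samples) + gap_samples
  x <- rnorm(n, i0, noise_sd)
  starts <- gap_samples + (0:(n_pulses - 1)) * (dwell_samples + gap_samples)
  level <- i0 * (1 - depth_pct / 100)
  for (s in starts)
    x[(s + 1):(s + dwell_samples)] <- rnorm(dwell_samples, level, noise_sd)
  list(trace = as_trace(x, fs, voltage = -50),
       starts = starts, dwell_samples = dwell_samples,
       depth_pct = depth_pct)
}

# feature library with two planted informative features among noise:
# classes differ only in feature 1 and 2
planted_feature_library <- function(n_classes = 3, n_noise = 6, sep = 2.5) {
  d <- 2 + n_noise
  feats <- c("inf1", "inf2", paste0("noise", seq_len(n_noise)))
  mu <- matrix(0, n_classes, d, dimnames = list(paste0("K", seq_len(n_classes)), feats))
  sd <- matrix(1, n_classes, d, dimnames = dimnames(mu))
  mu[, 1] <- sep * (seq_len(n_classes) - 1)
  mu[, 2] <- sep * rev(seq_len(n_classes) - 1)
  structure(list(labels = rownames(mu), features = feats,
                 mean = mu, sd = sd, provenance = "planted"),
            class = "feature_library")
}

# sample a labelled table from any feature_library-shaped object
sample_feature_table <- function(flib, n_per_class, seed = 1) {
  set.seed(seed)
  blocks <- lapply(seq_along(flib$labels), function(a) {
    m <- matrix(rnorm(n_per_class * length(flib$features),
                      mean = rep(flib$mean[a, ], each = n_per_class),
                      sd = rep(flib$sd[a, ], each = n_per_class)),
                nrow = n_per_class)
    colnames(m) <- flib$features
    m
  })
  out <- as.data.frame(do.call(rbind, blocks), check.names = FALSE)
  out$label <- factor(rep(flib$labels, each = n_per_class),
                      levels = flib$labels)
  out
}
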