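#' Conditioning settings of the frequency-modulated feature scheme
#'
#' @return character vector of the six conditioning names, base condition
#'   first.
#' @export
feature_conditions <- function() {
  c("lp2000", "lp800", "lp500", "lp200", "lp100", "wavelet")
}

#' Condition a current signal
#'
#' Applies one of the six conditioning settings used by the
#' frequency-modulated feature scheme: a zero-phase 4th-order
#' Butterworth low-pass at 2000/800/500/200/100 Hz, or wavelet denoising
#' (sym4, 4 levels, soft universal threshold). The low-pass is realized
#' spectrally with the forward-backward Butterworth gain
#' `1 / (1 + (f/fc)^8)` on a reflectively padded segment: exactly zero
#' phase, stable at any cutoff-to-length ratio (events can be far
#' shorter than the filter's impulse response), sample count and DC
#' level preserved.
#'
#' @param samples numeric current vector (whole trace or within-event
#'   samples), pA.
#' @param condition one of [feature_conditions()].
#' @param sampling_rate Hz (required for low-pass settings).
#' @return numeric vector, same length as `samples`.
#' @export
#' @examples
#' condition_signal(rep(-100, 64), "lp500", sampling_rate = 20000)
condition_signal <- function(samples, condition, sampling_rate = 20000) {
  condition <- match.arg(condition, feature_conditions())
  x <- as.numeric(samples)
  if (condition == "wavelet") return(wavelet_denoise(x))
  cutoff <- as.numeric(sub("^lp", "", condition))
  if (cutoff >= sampling_rate / 2)
    stop("cutoff ", cutoff, " Hz is at or above Nyquist (",
         sampling_rate / 2, " Hz)")
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(x)
  npad <- min(n - 1L, as.integer(3L * ceiling(sampling_rate / cutoff)))
  xp <- c(rev(x[2:(npad + 1)]), x, rev(x[(n - npad):(n - 1)]))
  m <- length(xp)
  freq <- (seq_len(m) - 1L)
  freq <- pmin(freq, m - freq) * sampling_rate / m
  gain <- 1 / (1 + (freq / cutoff)^8)
  y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / m
  y[npad + seq_len(n)]
}

# --- sym4 discrete wavelet transform ------------------------------------
# Symlet-4 (least-asymmetric Daubechies, 4 vanishing moments)
# decomposition low-pass coefficients.
.sym4_lo <- c(-0.07576571478927333, -0.02963552764599851,
              0.49761866763201545, 0.80373875180591614,
              0.29785779560527736, -0.09921954357684722,
              -0.01260396726203783, 0.03222310060404270)

# Periodic orthogonal analysis step: rows of the transform are even
# shifts of the filters, so the inverse is the transpose.
.dwt_step <- function(x, lo, hi) {
  n <- length(x)
  half <- n %/% 2
  k0 <- 2 * (seq_len(half) - 1L)
  a <- d <- numeric(half)
  for (m in seq_along(lo)) {
    xi <- x[((k0 + m - 1L) %% n) + 1L]
    a <- a + lo[m] * xi
    d <- d + hi[m] * xi
  }
  list(a = a, d = d)
}

.idwt_step <- function(a, d, lo, hi) {
  n <- 2L * length(a)
  k0 <- 2 * (seq_along(a) - 1L)
  y <- numeric(n)
  for (m in seq_along(lo)) {
    idx <- ((k0 + m - 1L) %% n) + 1L
    y[idx] <- y[idx] + lo[m] * a + hi[m] * d
  }
  y
}

#' Wavelet denoising of a current signal
#'
#' Periodic sym4 discrete wavelet transform to `levels` levels with soft
#' universal thresholding (`sigma * sqrt(2 log n)`, sigma from the MAD of
#' the finest detail coefficients). Approximation coefficients are left
#' untouched, so the DC level is preserved exactly.
#'
#' @param x numeric signal.
#' @param levels decomposition depth.
#' @return denoised signal, same length as `x`.
#' @export
wavelet_denoise <- function(x, levels = 4) {
  n0 <- length(x)
  if (n0 < 2^levels) return(x)
  lo <- .sym4_lo
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)     # quadrature mirror
  # pad to a multiple of 2^levels by reflection
  block <- 2^levels
  npad <- (block - n0 %% block) %% block
  xp <- if (npad > 0) c(x, rev(x)[seq_len(npad)]) else x
  approx <- xp
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    st <- .dwt_step(approx, lo, hi)
    approx <- st$a
    details[[l]] <- st$d
  }
  sigma <- stats::mad(details[[1]])
  thr <- sigma * sqrt(2 * log(length(xp)))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  for (l in seq_len(levels)) details[[l]] <- soft(details[[l]])
  for (l in rev(seq_len(levels)))
    approx <- .idwt_step(approx, details[[l]], lo, hi)
  approx[seq_len(n0)]
}
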