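#' Reference PFCA-probe analyte library
#'
#' Returns the built-in table of per- and polyfluoroalkyl carboxylic acid
#' (PFCA) probe conjugates used throughout the package. The eight linear
#' perfluoroalkyl acids C2--C9 (plus the bare hexa-arginine probe, C0)
#' anchor the linear volume--blockade relationship; the H- and
#' Cl-substituted polyfluoroalkyl acids (3H, 5H, 7H, 3Cl) and the 3:3
#' fluorotelomer acid (FTA) are the standard-free prediction targets.
#'
#' Volumes are hydrodynamic volumes of the probe conjugate in cubic
#' angstroms; they are inputs (typically from all-atom MD), never computed
#' here. The built-in values are synthetic: they are spaced exactly
#' 73.5 A^3 per -CF2- unit from a C2 conjugate volume of 1757.5 A^3, which
#' places the blockade means on the default calibration line (see
#' [build_default_library()]).
#'
#' @param subset optional character vector of labels to keep, in the given
#'   order.
#' @return data.frame with columns `label`, `formula` (free-acid elemental
#'   composition; `NA` for the bare probe), `volume` (A^3) and `n_cf2`
#'   (number of -CF2- units in excess of C2; `NA` where not applicable).
#' @export
#' @examples
#' pfca_analytes(c("C2", "C5", "C9"))
pfca_analytes <- function(subset = NULL) {
  v_c2 <- 1757.5
  u <- 73.5
  lib <- data.frame(
    label = c("C0", paste0("C", 2:9), "3H", "5H", "7H", "3Cl", "FTA"),
    formula = c(NA,
                "C2HF3O2", "C3HF5O2", "C4HF7O2", "C5HF9O2",
                "C6HF11O2", "C7HF13O2", "C8HF15O2", "C9HF17O2",
                "C3H2F4O2", "C5H2F8O2", "C7H2F12O2", "C3HClF4O2",
                "C6H5F7O2"),
    volume = c(v_c2 - 2 * u,
               v_c2 + u * (0:7),
               v_c2 + u - 9.5,        # 3H: H-for-F substitution shrinks
               v_c2 + 3 * u - 9.5,    # 5H
               v_c2 + 5 * u - 9.5,    # 7H
               v_c2 + u + 7.0,        # 3Cl: Cl larger than F
               2010.0),               # FTA sits between C5 and C6
    n_cf2 = c(NA, 0:7, 1, 3, 5, 1, NA),
    # relative within-event current-noise scale: H-substituted and
    # fluorotelomer conjugates are conformationally more flexible and
    # produce visibly noisier residence levels than perfluoro chains
    isd_scale = c(1, rep(1, 8), 1.1, 1.1, 1.1, 1.05, 1.25),
    stringsAsFactors = FALSE
  )
  if (!is.null(subset)) {
    miss <- setdiff(subset, lib$label)
    if (length(miss)) stop("unknown analyte label(s): ", paste(miss, collapse = ", "))
    lib <- lib[match(subset, lib$label), , drop = FALSE]
    rownames(lib) <- NULL
  }
  lib
}

# Default physical constants of the transduction model.
# Per -CF2- increment of blockade (%), unit volume (A^3) and the effective
# transduction volume (nm^3) at which the extrapolated blockade reaches 100%.
.pfca_defaults <- list(
  increment_pct    = 1.68,
  unit_volume_A3   = 73.5,
  effective_nm3    = 4.82,
  blockade_sd_pct  = 0.198,
  capture_constant = 2e5,    # events s^-1 per mol L^-1, probe-determined
  dwell_log_mean0  = log(1.5),  # log-ms at n_cf2 = 0
  dwell_log_slope  = 0.18,      # per -CF2- unit
  dwell_log_sd     = 0.35
)

#' Per-analyte signal parameters for the simulator
#'
#' Builds the per-analyte portion of a simulation configuration: blockade
#' mean and spread, log-normal dwell parameters, and capture constant.
#' Blockade means are an exact affine function of conjugate volume with a
#' slope of one per-unit increment (1.68% by default) per 73.5 A^3 -CF2-
#' unit; the intercept is fixed so that extrapolation to 100% blockade
#' occurs at the effective transduction volume (4.82 nm^3 by default).
#' Dwell-time location increases monotonically with chain length.
#'
#' @param analytes data.frame as returned by [pfca_analytes()]; each row
#'   needs `volume` or `n_cf2`.
#' @param concentration molar concentration(s), recycled across analytes
#'   (mol L^-1).
#' @param capture_constant events s^-1 per mol L^-1 (recycled). The
#'   probe-directed design makes this analyte-independent by default.
#' @param blockade_sd standard deviation of the per-event blockade (%).
#' @param increment_pct blockade increase per -CF2- unit (%).
#' @param unit_volume_A3 volume of one -CF2- unit (A^3).
#' @param effective_nm3 effective transduction volume (nm^3): the volume at
#'   which the blockade line reaches 100%.
#' @return data.frame with one row per analyte: `label`, `volume`,
#'   `concentration`, `capture_constant`, `blockade_mean`, `blockade_sd`,
#'   `dwell_log_mean`, `dwell_log_sd`.
#' @export
#' @examples
#' lib <- build_default_library(pfca_analytes(c("C2", "C3", "C9")))
#' diff(lib$blockade_mean)   # 1.68% per -CF2- spacing
build_default_library <- function(analytes,
                                  concentration = 1e-6,
                                  capture_constant = .pfca_defaults$capture_constant,
                                  blockade_sd = .pfca_defaults$blockade_sd_pct,
                                  increment_pct = .pfca_defaults$increment_pct,
                                  unit_volume_A3 = .pfca_defaults$unit_volume_A3,
                                  effective_nm3 = .pfca_defaults$effective_nm3) {
  stopifnot(is.data.frame(analytes), nrow(analytes) >= 1)
  if (is.null(analytes$volume) && is.null(analytes$n_cf2))
    stop("analytes need a 'volume' or 'n_cf2' column")
  vol <- analytes$volume
  if (is.null(vol)) vol <- rep(NA_real_, nrow(analytes))
  ncf <- analytes$n_cf2
  if (is.null(ncf)) ncf <- rep(NA_real_, nrow(analytes))
  # volume from n_cf2 when missing (anchored at the built-in C2 volume)
  vol[is.na(vol)] <- 1757.5 + unit_volume_A3 * ncf[is.na(vol)]
  if (anyNA(vol))
    stop("analyte(s) without volume or n_cf2: ",
         paste(analytes$label[is.na(vol)], collapse = ", "))
  slope <- increment_pct / unit_volume_A3               # % per A^3
  intercept <- 100 - slope * (effective_nm3 * 1000)     # % at V = 0
  blockade <- intercept + slope * vol
  if (any(blockade <= 0 | blockade >= 100))
    stop("blockade mean outside (0, 100)%% for: ",
         paste(analytes$label[blockade <= 0 | blockade >= 100], collapse = ", "))
  # dwell location from chain length; analytes without n_cf2 (probe, FTA)
  # fall back to a volume-equivalent chain length
  ncf_eff <- ifelse(is.na(ncf), (vol - 1757.5) / unit_volume_A3, ncf)
  d <- .pfca_defaults
  out <- data.frame(
    label = analytes$label,
    volume = vol,
    concentration = rep_len(concentration, nrow(analytes)),
    capture_constant = rep_len(capture_constant, nrow(analytes)),
    blockade_mean = blockade,
    blockade_sd = rep_len(blockade_sd, nrow(analytes)),
    dwell_log_mean = d$dwell_log_mean0 + d$dwell_log_slope * ncf_eff,
    dwell_log_sd = rep_len(d$dwell_log_sd, nrow(analytes)),
    stringsAsFactors = FALSE
  )
  if (!is.null(analytes$isd_scale)) out$isd_scale <- analytes$isd_scale
  rownames(out) <- NULL
  out
}

# Atomic weights (IUPAC 2021 conventional values) for formula parsing.
.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998403,
  Na = 22.98977, P = 30.973762, S = 32.06, Cl = 35.45, K = 39.0983,
  Br = 79.904, I = 126.90447
)

#' Molar mass from an elemental formula
#'
#' Parses a simple Hill-style elemental composition string (e.g.
#' `"C2HF3O2"` for trifluoroacetic acid) and sums standard atomic weights.
#'
#' @param formula composition string; element symbols with optional counts.
#' @return molar mass in g mol^-1.
#' @export
#' @examples
#' molar_mass("C2HF3O2")   # trifluoroacetic acid, ~114.02 g/mol
molar_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  total <- 0
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    cnt <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(cnt)) as.numeric(cnt) else 1
    w <- .atomic_weights[sym]
    if (is.na(w)) stop("unknown element symbol '", sym, "' in formula ", formula)
    total <- total + n * w
  }
  unname(total)
}
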