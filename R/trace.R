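#' Construct a current trace object
#'
#' A `trace` is the raw sensor signal: a numeric vector of sampled ionic
#' current (pA, signed) with acquisition metadata.
#'
#' @param samples numeric current samples, pA.
#' @param sampling_rate Hz.
#' @param voltage applied bias, mV.
#' @param temperature degrees C.
#' @param metadata free-form named list (pore variant, electrolyte, ...).
#' @return object of class `trace`.
#' @export
as_trace <- function(samples, sampling_rate, voltage = NA_real_,
                     temperature = 20, metadata = list()) {
  stopifnot(is.numeric(samples), length(samples) > 0, sampling_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 voltage = voltage, temperature = temperature,
                 metadata = metadata),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g Hz (%.3f s), %g mV\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$voltage))
  invisible(x)
}

#' Write a trace to disk
#'
#' Columnar text format: `# key=value` header lines followed by one
#' current value (pA) per line. The binary variant stores the same object
#' in a compact serialized container.
#'
#' @param trace a [as_trace()] object.
#' @param path output file.
#' @param format `"text"` or `"binary"`.
#' @export
write_trace <- function(trace, path, format = c("text", "binary")) {
  format <- match.arg(format)
  stopifnot(inherits(trace, "trace"))
  if (format == "binary") {
    saveRDS(trace, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz=%.10g", trace$sampling_rate),
               sprintf("# voltage_mv=%.10g", trace$voltage),
               sprintf("# temperature_c=%.10g", trace$temperature)), con)
  for (k in names(trace$metadata))
    writeLines(sprintf("# meta.%s=%s", k, as.character(trace$metadata[[k]])), con)
  writeLines(format(trace$samples, digits = 17, scientific = FALSE,
                    trim = TRUE), con)
  invisible(path)
}

#' Read a trace from disk
#'
#' @param path file written by [write_trace()].
#' @param format `"text"` or `"binary"`.
#' @return a `trace` object.
#' @export
read_trace <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "binary") {
    tr <- readRDS(path)
    if (!inherits(tr, "trace")) stop("not a trace container: ", path)
    return(tr)
  }
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  header <- lines[hdr]
  kv <- sub("^#\\s*", "", header)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  need <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("trace header missing '", k, "' in ", path)
    vals[i]
  }
  fs <- suppressWarnings(as.numeric(need("sampling_rate_hz")))
  if (is.na(fs)) stop("malformed sampling_rate_hz header in ", path)
  volt <- suppressWarnings(as.numeric(need("voltage_mv")))
  temp_i <- match("temperature_c", keys)
  temp <- if (is.na(temp_i)) 20 else as.numeric(vals[temp_i])
  meta_i <- grep("^meta\\.", keys)
  metadata <- as.list(vals[meta_i])
  names(metadata) <- sub("^meta\\.", "", keys[meta_i])
  # metadata values stored as text; coerce numerics back where possible
  metadata <- lapply(metadata, function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  body <- lines[!hdr]
  body <- body[nzchar(trimws(body))]
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[1]
    stop("malformed current value at data line ", bad, " of ", path)
  }
  as_trace(samples, sampling_rate = fs, voltage = volt,
           temperature = temp, metadata = metadata)
}

#' Write / read an event table
#'
#' Delimited text with header `event_id, start_s, dwell_ms, blockade_pct,
#' label` (extra columns preserved).
#'
#' @param events data.frame of events.
#' @param path file path.
#' @rdname event_table_io
#' @export
write_event_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname event_table_io
#' @export
read_event_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df
}

#' Write / read a feature table
#'
#' Delimited text with the 43 systematic feature columns
#' (`<feature>@<condition>`, `tau_on`) plus any of `label`, `event_id`,
#' `batch`.
#'
#' @param features data.frame from the feature extractor.
#' @param path file path.
#' @rdname feature_table_io
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname feature_table_io
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(feature_names(), names(df))
  if (length(missing))
    stop("feature table ", path, " missing column(s): ",
         paste(missing, collapse = ", "))
  if ("label" %in% names(df)) df$label <- factor(df$label)
  df
}
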