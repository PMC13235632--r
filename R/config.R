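# Processing configuration: TOML-style sectioned key = value text files.
# Unknown sections or keys are errors (fail-fast: silent defaults are the
# main source of irreproducible spectra). Every key has a default except the
# input/output paths.

.CONFIG_SCHEMA <- list(
  input = c("path"),
  output = c("path", "report", "format", "truth", "scan", "peaks"),
  process = c("mode"),
  apod = c("f2_kind", "f2_f", "f2_sine_shift",
           "f1_kind", "f1_f", "f1_sine_shift"),
  zerofill = c("f1", "f2"),
  phase = c("a0", "a1", "a2", "b0", "b1"),
  baseline = c("enabled", "order", "n_replace"),
  calibration = c("source", "csv"),
  peaks = c("threshold"),
  noise = c("region_start", "region_end"),
  extract = c("kind", "mz"),
  simulate = c("seed", "tau", "noise_sigma", "scint_fraction",
               "magnetic_field", "n_t1", "dt1", "n_t2", "sample_rate_t2",
               "f1_offset", "precursors_csv")
)

.CONFIG_DEFAULTS <- list(
  process = list(mode = "absorption"),
  apod = list(f2_kind = "kv_asymmetric_sqrt_fall", f2_f = 0.25,
              f2_sine_shift = 0, f1_kind = "none", f1_f = 0.25,
              f1_sine_shift = 0),
  zerofill = list(f1 = 0L, f2 = 0L),
  phase = list(a0 = 0, a1 = 0, a2 = 0, b0 = 0, b1 = 0),
  baseline = list(enabled = FALSE, order = "auto", n_replace = 0L),
  calibration = list(source = "theoretical", csv = NULL),
  peaks = list(threshold = 3),
  noise = list(region_start = NULL, region_end = NULL),
  simulate = list(seed = 1L, tau = 0.05, noise_sigma = 0,
                  scint_fraction = 0, magnetic_field = 15, n_t1 = 64L,
                  dt1 = 2e-6, n_t2 = 1024L, sample_rate_t2 = 1e6,
                  f1_offset = 0, precursors_csv = NULL)
)

.parseValue <- function(s) {
  s <- trimws(s)
  if (grepl('^".*"$', s)) return(substr(s, 2, nchar(s) - 1))
  if (tolower(s) %in% c("true", "false")) return(tolower(s) == "true")
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n)) return(n)
  s
}

#' Read a processing configuration file
#'
#' Sectioned key = value text (\code{[section]} headers, \code{#} comments,
#' quoted or bare strings, numbers, \code{true}/\code{false}). Unknown
#' sections or keys raise a named config error.
#'
#' @param path config file path.
#' @return nested named list with defaults filled in.
#' @export
readProcessingConfig <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  cfg <- .CONFIG_DEFAULTS
  section <- NULL
  for (ln in readLines(path, warn = FALSE)) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(.CONFIG_SCHEMA))
        stop("config error: unknown section [", section, "]")
      next
    }
    if (!grepl("=", ln, fixed = TRUE) || is.null(section))
      stop("config error: expected 'key = value' inside a section, got: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    if (!key %in% .CONFIG_SCHEMA[[section]])
      stop(sprintf("config error: unknown key '%s' in section [%s]",
                   key, section))
    cfg[[section]][[key]] <- .parseValue(sub("^[^=]*=", "", ln))
  }
  cfg
}

.configApod <- function(cfg, dim) {
  apodizationSpec(cfg$apod[[paste0(dim, "_kind")]],
                  F = cfg$apod[[paste0(dim, "_f")]],
                  sineShift = cfg$apod[[paste0(dim, "_sine_shift")]])
}

.configPhase <- function(cfg) {
  do.call(phaseFunction2d, cfg$phase[c("a0", "a1", "a2", "b0", "b1")])
}

.configCalibration <- function(cfg, params) {
  if (identical(cfg$calibration$source, "theoretical"))
    return(theoreticalCalibration(params@magneticField))
  if (identical(cfg$calibration$source, "csv")) {
    if (is.null(cfg$calibration$csv))
      stop("config error: calibration.source = csv requires calibration.csv")
    tab <- utils::read.csv(cfg$calibration$csv)
    if (!all(c("frequency_hz", "mz") %in% names(tab)))
      stop("config error: calibrant CSV needs columns frequency_hz, mz")
    return(fitCalibration(tab$frequency_hz, tab$mz))
  }
  stop("config error: calibration.source must be theoretical or csv")
}
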