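# Config-driven batch drivers tying the stages into the two-pass
# out-of-core pipeline, with a text run report. These are the functions the
# command-line entry point (inst/scripts/ftms2d.R) wraps.

.runReport <- function(path, lines) {
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

.gridChecksum <- function(d) {
  # order-independent fingerprint accumulated row by row
  s <- 0; ss <- 0
  n <- gridDims(d)
  for (i in seq_len(n[1])) {
    v <- scanValues(getRow(d, i))
    if (is.complex(v)) v <- c(Re(v), Im(v))
    s <- s + sum(v); ss <- ss + sum(v^2)
    noteBufferCycle()
  }
  sprintf("sum=%.10e l2=%.10e", s, sqrt(ss))
}

#' Run the processing pipeline from a configuration
#'
#' Opens the raw data set, executes the row pass (apodization, zerofill, F2
#' transform, quadratic phase) and the column pass (baseline correction, F1
#' transform, linear phase or hypercomplex modulus) under the
#' one-row/one-column memory contract, writes the processed data set and a
#' text run report. Identical config + input gives identical output.
#'
#' @param config path to a config file or a list from
#'   \code{\link{readProcessingConfig}}.
#' @return the processed \code{\linkS4class{Dataset2D}}, invisibly.
#' @export
runProcess <- function(config) {
  cfg <- if (is.character(config)) readProcessingConfig(config) else config
  if (is.null(cfg$input$path))
    stop("config error: input.path is required")
  if (!file.exists(cfg$input$path) &&
      !file.exists(paste0(sub("\\.(params|bin)$", "", cfg$input$path), ".params")))
    stop("config error: input path does not exist: ", cfg$input$path)
  raw <- openDataset(cfg$input$path)
  mode <- cfg$process$mode
  if (!mode %in% c("absorption", "magnitude"))
    stop("config error: process.mode must be absorption or magnitude")
  t0 <- Sys.time()
  fun <- if (mode == "absorption") absorption2d else magnitude2d
  blOrder <- if (isTRUE(cfg$baseline$enabled)) {
    if (identical(cfg$baseline$order, "auto")) "auto"
    else as.integer(cfg$baseline$order)
  } else 0L
  out <- fun(raw, .configPhase(cfg),
             apodF2 = .configApod(cfg, "f2"), apodF1 = .configApod(cfg, "f1"),
             zerofillF2 = as.integer(cfg$zerofill$f2),
             zerofillF1 = as.integer(cfg$zerofill$f1),
             baselineOrder = blOrder,
             baselineNReplace = as.integer(cfg$baseline$n_replace))
  t1 <- Sys.time()
  if (!is.null(cfg$output$path))
    writeDataset(out, cfg$output$path,
                 format = if (!is.null(cfg$output$format)) cfg$output$format
                          else "auto")
  t2 <- Sys.time()
  d <- gridDims(out)
  .runReport(cfg$output$report, c(
    sprintf("mode: %s", mode),
    sprintf("input: %s", cfg$input$path),
    sprintf("grid: %d x %d (row pass + column pass completed)", d[1], d[2]),
    sprintf("apodization: F2 %s (F=%g), F1 %s", cfg$apod$f2_kind,
            cfg$apod$f2_f, cfg$apod$f1_kind),
    sprintf("zerofills: F1 %d, F2 %d", cfg$zerofill$f1, cfg$zerofill$f2),
    sprintf("phase: a0=%g a1=%g a2=%g b0=%g b1=%g", cfg$phase$a0,
            cfg$phase$a1, cfg$phase$a2, cfg$phase$b0, cfg$phase$b1),
    sprintf("baseline: enabled=%s order=%s n_replace=%s",
            cfg$baseline$enabled, cfg$baseline$order, cfg$baseline$n_replace),
    sprintf("timing: transform %.2f s, write %.2f s",
            as.numeric(difftime(t1, t0, units = "secs")),
            as.numeric(difftime(t2, t1, units = "secs"))),
    sprintf("checksum: %s", .gridChecksum(out))))
  invisible(out)
}

.readPrecursorsCsv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("precursor_mz", "fragment_mz", "efficiency")
  if (!all(need %in% names(tab)))
    stop("config error: precursor CSV needs columns ",
         paste(need, collapse = ", "))
  if (is.null(tab$abundance)) tab$abundance <- 1
  if (is.null(tab$charge)) tab$charge <- 1L
  lapply(split(tab, tab$precursor_mz), function(g) {
    frags <- lapply(which(!is.na(g$fragment_mz)), function(r)
      c(mz = g$fragment_mz[r], charge = g$charge[r],
        efficiency = g$efficiency[r]))
    precursorSpec(g$precursor_mz[1], charge = g$charge[1],
                  abundance = g$abundance[1], fragments = frags)
  })
}

#' Simulate a raw data set from a configuration
#'
#' Thin wrapper over \code{\link{generateDataset2d}} with file output:
#' writes the raw data set (flat-binary or HDF5 by extension) and the
#' ground-truth line table as CSV. A fixed seed gives identical output
#' across runs.
#'
#' @param config config path or list; uses the \code{[simulate]} section
#'   plus \code{output.path} / \code{output.truth}.
#' @return list(dataset, truth), invisibly.
#' @export
runSimulate <- function(config) {
  cfg <- if (is.character(config)) readProcessingConfig(config) else config
  s <- cfg$simulate
  if (is.null(s$precursors_csv))
    stop("config error: simulate.precursors_csv is required")
  precursors <- .readPrecursorsCsv(s$precursors_csv)
  acq <- acquisitionParams(s$magnetic_field, s$n_t1, s$dt1, s$n_t2,
                           s$sample_rate_t2, f1Offset = s$f1_offset)
  sc <- simConfig(acq, precursors, tau = s$tau,
                  noiseSigma = s$noise_sigma,
                  scintFraction = s$scint_fraction, seed = s$seed)
  sim <- generateDataset2d(sc, backing = "file")
  if (!is.null(cfg$output$path)) writeDataset(sim$dataset, cfg$output$path)
  if (!is.null(cfg$output$truth))
    utils::write.csv(sim$truth, cfg$output$truth, row.names = FALSE)
  invisible(sim)
}

#' Extract a scan from a processed data set
#'
#' Thin wrapper over the extraction operations with file I/O: reads the
#' processed data set named by \code{input.path}, extracts the scan named
#' by the \code{[extract]} section (\code{kind} = fragment, precursor or
#' autocorrelation; \code{mz} target), and writes it as CSV to
#' \code{output.scan}.
#'
#' @param config config path or list.
#' @return the \code{\linkS4class{Scan}}, invisibly.
#' @export
runExtract <- function(config) {
  cfg <- if (is.character(config)) readProcessingConfig(config) else config
  if (is.null(cfg$input$path)) stop("config error: input.path is required")
  d <- openDataset(cfg$input$path)
  cal <- .configCalibration(cfg, d@params)
  kind <- cfg$extract$kind
  s <- switch(kind,
    fragment = extractFragmentScan(d, cfg$extract$mz, cal),
    precursor = extractPrecursorScan(d, cfg$extract$mz, cal),
    autocorrelation = autocorrelationLine(d, cal),
    stop("config error: extract.kind must be fragment, precursor or autocorrelation"))
  if (!is.null(cfg$output$scan)) writeScanCsv(s, cfg$output$scan)
  invisible(s)
}

#' Pick 2D peaks from a processed data set
#'
#' Thin wrapper over \code{\link{pickPeaks2d}} with file I/O; writes the
#' peak list CSV to \code{output.peaks}.
#'
#' @param config config path or list.
#' @return the peak data frame, invisibly.
#' @export
runPeaks <- function(config) {
  cfg <- if (is.character(config)) readProcessingConfig(config) else config
  if (is.null(cfg$input$path)) stop("config error: input.path is required")
  d <- openDataset(cfg$input$path)
  cal <- .configCalibration(cfg, d@params)
  noise <- NULL
  if (!is.null(cfg$noise$region_start) && !is.null(cfg$noise$region_end)) {
    # noise from a user-specified empty segment of the first row
    noise <- noiseLevel(getRow(d, 1L),
                        c(cfg$noise$region_start, cfg$noise$region_end))@level
  }
  peaks <- pickPeaks2d(d, thresholdMultiple = cfg$peaks$threshold,
                       noise = noise, calF1 = cal)
  if (!is.null(cfg$output$peaks)) writePeaksCsv(peaks, cfg$output$peaks)
  invisible(peaks)
}
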