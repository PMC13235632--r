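# Elemental formulas, cyclotron-frequency physics and quadratic
# frequency-to-m/z calibration.

#' Parse a Hill-notation elemental formula
#'
#' Accepts formulas like \code{"C32H42N5O5+"}: element symbols with counts,
#' followed by an optional trailing charge (\code{"+"}, \code{"-"},
#' \code{"2+"}, \code{"3-"}).
#'
#' @param formula formula string.
#' @return list with \code{counts} (named integer vector) and \code{charge}.
#' @examples
#' parseFormula("C32H42N5O5+")
#' @export
parseFormula <- function(formula) {
  s <- trimws(formula)
  charge <- 0L
  # trailing digits belong to the charge only when unambiguous: "+2"
  # (sign first), "C6H12O6 2+" (space-separated), or bare signs "+"/"--"
  if (grepl("[+-][0-9]+$", s)) {
    m <- regmatches(s, regexec("([+-])([0-9]+)$", s))[[1]]
    charge <- (if (m[2] == "+") 1L else -1L) * as.integer(m[3])
    s <- sub("[+-][0-9]+$", "", s)
  } else if (grepl("\\s[0-9]*[+-]+$", s)) {
    m <- regmatches(s, regexec("\\s([0-9]*)([+-]+)$", s))[[1]]
    sign <- if (substr(m[3], 1, 1) == "+") 1L else -1L
    charge <- sign * (if (nzchar(m[2])) as.integer(m[2]) else nchar(m[3]))
    s <- sub("\\s[0-9]*[+-]+$", "", s)
  } else if (grepl("[+-]+$", s)) {
    m <- regmatches(s, regexpr("[+-]+$", s))
    charge <- (if (substr(m, 1, 1) == "+") 1L else -1L) * nchar(m)
    s <- sub("[+-]+$", "", s)
  }
  s <- gsub("\\s", "", s)
  if (!nzchar(s)) stop("validation error: empty formula")
  toks <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  if (sum(nchar(toks)) != nchar(s))
    stop("validation error: cannot parse formula: ", formula)
  counts <- integer(0)
  for (t in toks) {
    el <- regmatches(t, regexpr("^[A-Z][a-z]?", t))
    n <- sub("^[A-Z][a-z]?", "", t)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
  }
  if (sum(counts) < 1L) stop("validation error: formula has no atoms")
  list(counts = counts, charge = charge)
}

#' Monoisotopic mass-to-charge ratio of an elemental formula
#'
#' Sums monoisotopic atomic masses, subtracts \code{charge} electron masses,
#' and divides by \code{|charge|}. With charge 0 the neutral monoisotopic
#' mass is returned.
#'
#' @param formula a formula string (see \code{\link{parseFormula}}) or a
#'   parsed list.
#' @param charge optional charge override.
#' @return m/z in thomson (neutral mass in u for charge 0).
#' @examples
#' monoisotopicMz("C32H42N5O5+")  # protonated ergocryptine fragment ion
#' @export
monoisotopicMz <- function(formula, charge = NULL) {
  f <- if (is.character(formula)) parseFormula(formula) else formula
  if (!is.null(charge)) f$charge <- as.integer(charge)
  unknown <- setdiff(names(f$counts), names(.MONO_MASS))
  if (length(unknown))
    stop("validation error: unknown element symbol(s): ",
         paste(unknown, collapse = ", "))
  mass <- sum(f$counts * .MONO_MASS[names(f$counts)]) -
    f$charge * .ELECTRON_MASS_U
  if (f$charge == 0L) mass else mass / abs(f$charge)
}

#' Unperturbed cyclotron frequency and its inverse
#'
#' f = eB / (2 pi u (m/z)) with the elementary charge e and the atomic mass
#' constant u (CODATA 2018). \code{mzFromFrequency} is the exact inverse.
#'
#' @param mz mass-to-charge ratio, thomson (> 0).
#' @param B magnetic field, tesla (> 0).
#' @param f frequency, Hz (> 0).
#' @return frequency in Hz (or m/z in Th for the inverse).
#' @examples
#' cyclotronFrequency(592.29182, 15) - cyclotronFrequency(592.25542, 15)
#' @export
cyclotronFrequency <- function(mz, B) {
  if (any(mz <= 0) || any(B <= 0))
    stop("validation error: mz and B must be > 0")
  .ELEMENTARY_CHARGE * B / (2 * pi * .ATOMIC_MASS_UNIT * mz)
}

#' @rdname cyclotronFrequency
#' @export
mzFromFrequency <- function(f, B) {
  if (any(f <= 0) || any(B <= 0))
    stop("validation error: f and B must be > 0")
  .ELEMENTARY_CHARGE * B / (2 * pi * .ATOMIC_MASS_UNIT * f)
}

#' Fit the quadratic frequency-to-m/z calibration
#'
#' Least-squares fit of m/z = c1/f + c2/f^2 to calibrant (frequency, m/z)
#' pairs. With exactly two points the fit is exact; with more it is the
#' ordinary least-squares solution in the (1/f, 1/f^2) basis.
#'
#' @param freq calibrant frequencies, Hz (distinct, >= 2).
#' @param mz known m/z values, Th.
#' @return a \code{\linkS4class{CalibrationQuadratic}} whose validity
#'   interval spans the calibrant frequencies.
#' @examples
#' cal <- fitCalibration(c(2e5, 4e5), c(1151.8, 575.9))
#' freqToMz(cal, 3e5)
#' @export
fitCalibration <- function(freq, mz) {
  if (length(freq) < 2L)
    stop("fit error: at least 2 calibration points required")
  if (length(freq) != length(mz))
    stop("fit error: freq and mz lengths differ")
  if (anyDuplicated(freq))
    stop("singular-system error: duplicate calibration frequencies")
  X <- cbind(1 / freq, 1 / freq^2)
  beta <- qr.coef(qr(X), mz)
  new("CalibrationQuadratic", c1 = beta[[1]], c2 = beta[[2]],
      fRange = range(freq))
}

#' Ideal calibration from the magnetic field
#'
#' The theoretical one-term law m/z = (eB / 2 pi u) / f as a
#' \code{CalibrationQuadratic} with c2 = 0; useful for simulated data where
#' the unperturbed cyclotron relation holds exactly.
#'
#' @param B magnetic field, tesla.
#' @param fRange validity interval, Hz.
#' @return a \code{CalibrationQuadratic}.
#' @export
theoreticalCalibration <- function(B, fRange = c(1e3, 1e7)) {
  new("CalibrationQuadratic",
      c1 = .ELEMENTARY_CHARGE * B / (2 * pi * .ATOMIC_MASS_UNIT),
      c2 = 0, fRange = as.numeric(fRange))
}

#' Apply or invert a quadratic calibration
#'
#' \code{freqToMz} evaluates m/z = c1/f + c2/f^2. \code{mzToFreq} inverts it
#' by solving the quadratic in f (m z f^2 - c1 f - c2 = 0) and taking the
#' root inside (or nearest) the calibration's validity interval.
#'
#' @param cal a \code{\linkS4class{CalibrationQuadratic}}.
#' @param f frequency values, Hz.
#' @param mz m/z values, Th.
#' @return m/z values (\code{freqToMz}) or frequencies (\code{mzToFreq}).
#' @export
freqToMz <- function(cal, f) {
  if (any(f <= 0)) stop("validation error: frequencies must be > 0")
  cal@c1 / f + cal@c2 / f^2
}

#' @rdname freqToMz
#' @export
mzToFreq <- function(cal, mz) {
  if (any(mz <= 0)) stop("validation error: m/z must be > 0")
  disc <- cal@c1^2 + 4 * mz * cal@c2
  if (any(disc < 0))
    stop("validation error: m/z outside the invertible range of the calibration")
  r1 <- (cal@c1 + sqrt(disc)) / (2 * mz)
  r2 <- (cal@c1 - sqrt(disc)) / (2 * mz)
  # prefer the positive root closest to the ideal c1/mz law
  ideal <- cal@c1 / mz
  ifelse(r1 > 0 & (r2 <= 0 | abs(r1 - ideal) <= abs(r2 - ideal)), r1, r2)
}
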