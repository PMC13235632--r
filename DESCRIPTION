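Package: ftms2d
Title: Out-of-Core Absorption-Mode Processing of Two-Dimensional FT-ICR Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Processing chain for broadband two-dimensional Fourier transform
    ion cyclotron resonance mass spectrometry (2D FT-ICR MS). Implements
    asymmetric apodization windows, the double Fourier transformation with
    quadratic phase correction in the fragment dimension and linear phase
    correction in the precursor dimension, autoregressive backward-prediction
    baseline correction of precursor ion scans, quadratic frequency-to-m/z
    calibration, scan extraction, and two-dimensional peak picking and
    centroiding. All grid operations honour a one-row/one-column out-of-core
    memory contract so data sets larger than RAM can be processed. A synthetic
    transient simulator with known ground truth makes every stage testable
    without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, rhdf5
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'backend.R'
    'dataset.R'
    'io.R'
    'chem.R'
    'apodize.R'
    'transform.R'
    'phase_optim.R'
    'baseline.R'
    'simulate.R'
    'analyze.R'
    'config.R'
    'pipeline.R'
RoxygenNote: 7.3.3
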