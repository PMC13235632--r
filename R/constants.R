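# Physical constants (CODATA 2018) and monoisotopic atomic masses.
# e is exact in the 2019 SI; u and m_e carry CODATA 2018 uncertainties far
# below the 1e-7 Th level relevant to FT-ICR calibration.

.ELEMENTARY_CHARGE <- 1.602176634e-19    # C (exact)
.ATOMIC_MASS_UNIT  <- 1.66053906660e-27  # kg
.ELECTRON_MASS_U   <- 5.48579909065e-4   # u

# Monoisotopic masses of the most abundant isotope, u (AME-consistent,
# >= 7 decimals where known).
.MONO_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.9720710015,
  P  = 30.9737616320,
  Na = 22.9897692809,
  K  = 38.9637064864,
  Cl = 34.9688527100,
  F  = 18.9984031630,
  Se = 79.9165218000,
  Fe = 55.9349375000,
  Li = 7.0160034366,
  Br = 78.9183376000,
  I  = 126.9044719000,
  Si = 27.9769265350,
  B  = 11.0093053700
)
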