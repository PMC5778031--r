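# Internal unit system: length in Angstrom, time in fs, charge in elementary
# charge e, energy in kJ/mol, mass in amu.  Wavenumbers are cm^-1 throughout.

# speed of light in cm/fs: nu[cm^-1] = f[fs^-1] / .c_cmfs
.c_cmfs <- 2.99792458e-5

# Boltzmann constant, kJ mol^-1 K^-1
.kB <- 8.31446261815324e-3

# Coulomb constant, kJ mol^-1 A e^-2
.ke_coulomb <- 1389.35457644382

# 1 amu A^2 fs^-2 in kJ/mol (kinetic-energy conversion)
.md_energy <- 1.66053906660e-27 * 6.02214076e23 * 1e7

.atomic_masses <- c(H = 1.00794, O = 15.9994, X = 0)

#' Convert a frequency in fs^-1 to a wavenumber in cm^-1
#' @param f frequency, fs^-1
#' @return wavenumber, cm^-1
#' @keywords internal
#' @noRd
freq_to_wavenumber <- function(f) f / .c_cmfs

#' @noRd
wavenumber_to_freq <- function(nu) nu * .c_cmfs

# Deterministic substream seed derived from a root seed and a stream label,
# kept within 32-bit integer range.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}
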