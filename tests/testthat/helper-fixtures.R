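# fixture builders shared across test files; everything is generated in code

triple <- function() {
  list(d = synthetic_fluorophore("mTRQ2"),
       a1 = synthetic_fluorophore("mVEN"),
       a2 = synthetic_fluorophore("mRFP"))
}

# write a spectrum CSV of a Gaussian (or arbitrary values) to a temp file
write_spectrum_csv <- function(wl, value, path = tempfile(fileext = ".csv")) {
  utils::write.csv(data.frame(wavelength_nm = wl, value = value), path,
                   row.names = FALSE)
  path
}

gaussian_csv <- function(mu = 520, sigma = 20, wl = seq(400, 700, 1),
                         scale = 1) {
  write_spectrum_csv(wl, scale * dnorm(wl, mu, sigma))
}

default_metadata <- function() {
  list(name = "test", quantum_yield = 0.6, lifetime_ns = 3.0)
}

# binned per-member component integrals of a simulated spectrum: the ground
# truth that unmixing coefficients must recover
component_bin_totals <- function(sim, dialect) {
  vapply(colnames(sim$components), function(m)
    sum(bin_spectrum(list(wavelengths = sim$wavelengths,
                          total = sim$components[, m]), dialect)$intensity),
    numeric(1))
}

paper_r0_triple <- c(5.7, 5.2, 5.1)
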