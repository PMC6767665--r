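# Shared fixtures: everything is generated in code at test time.

# wavenumber-linear grid + mirror-experiment dispersion phase
oct_grid <- function(n = 1024L) {
  build_grid(spectrometer_spec(n_pixels = n), dialect = "wavenumber")
}

oct_phase <- function(n = 1024L, disp = dispersion_spec()) {
  dispersion_phase(oct_grid(n), disp)
}

# the canonical three-reflector sparse signal
oct_sparse_signal <- function(n = 1024L) {
  sparse_reflectors(c(200L, 250L, 580L), c(3, 1, 0.1), n)
}

# dense-matrix oracle for the dispersion-compensated depth transform:
# inverse-DFT matrix x diagonal phase x f
dense_de_oracle <- function(f, phase, r_reference = 0.5) {
  n <- length(f)
  jk <- outer(0:(n - 1), 0:(n - 1))
  W <- exp(2i * pi * jk / n) / n
  as.vector(W %*% (exp(-1i * phase) * f)) / r_reference
}
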