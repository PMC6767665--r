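#' Spectrometer specification
#'
#' Describes the detection spectrometer: the centre of its band, the full
#' bandwidth it covers, its resolvable spectral element, and the number of
#' pixels read out. The defaults are the parameters of the dual-channel
#' system this package models (790 nm centre, 40 nm bandwidth, 0.05 nm
#' resolution, 960 pixels).
#'
#' @param center_wavelength Centre wavelength, nm.
#' @param bandwidth Full spectral bandwidth, nm.
#' @param spectral_resolution Resolvable spectral element, nm.
#' @param n_pixels Number of spectrometer pixels used.
#' @return An object of class `spectrometer_spec`.
#' @export
#' @examples
#' spectrometer_spec()
#' spectrometer_spec(790, 40, 0.05, 1024)
spectrometer_spec <- function(center_wavelength = 790,
                              bandwidth = 40,
                              spectral_resolution = 0.05,
                              n_pixels = 960) {
  stopifnot(length(center_wavelength) == 1, length(bandwidth) == 1,
            length(spectral_resolution) == 1, length(n_pixels) == 1)
  if (!all(is.finite(c(center_wavelength, bandwidth, spectral_resolution, n_pixels))) ||
      center_wavelength <= 0 || bandwidth <= 0 || spectral_resolution <= 0 ||
      n_pixels <= 0) {
    abort("all spectrometer_spec fields must be strictly positive and finite")
  }
  if (bandwidth <= spectral_resolution) {
    abort("bandwidth must exceed the spectral resolution")
  }
  n_pixels <- as.integer(n_pixels)
  if (n_pixels < 8) abort("n_pixels must be at least 8")
  structure(
    list(center_wavelength = center_wavelength,
         bandwidth = bandwidth,
         spectral_resolution = spectral_resolution,
         n_pixels = n_pixels),
    class = "spectrometer_spec"
  )
}

#' @export
print.spectrometer_spec <- function(x, ...) {
  cat(sprintf(
    "<spectrometer_spec> %g nm centre, %g nm bandwidth, %g nm resolution, %d pixels\n",
    x$center_wavelength, x$bandwidth, x$spectral_resolution, x$n_pixels))
  invisible(x)
}

#' Build a spectrometer pixel grid
#'
#' Lays out the pixel axis across the band
#' `[center - bandwidth/2, center + bandwidth/2]`, linearly in either
#' wavelength (as a grating spectrometer samples) or wavenumber (the
#' natural variable of the depth-encoding Fourier transform). The derived
#' axes are computed exactly from the linear one: `omega = 2*pi*c/lambda`,
#' `k = 2*pi/lambda`.
#'
#' Rows are ordered by increasing wavelength in both dialects, so wavenumber
#' and angular frequency decrease down the table.
#'
#' @param spec A [spectrometer_spec()].
#' @param dialect `"wavenumber"` (grid linear in k; the simulation default,
#'   which makes the discrete Fourier transform of the forward model exact)
#'   or `"wavelength"` (grid linear in lambda, as measured frames come off a
#'   grating spectrometer).
#' @return A `spectral_grid`: a tibble with columns `pixel` (1-based),
#'   `wavelength_nm`, `omega` (rad/s) and `k` (rad/m), carrying the spec and
#'   dialect as attributes.
#' @export
#' @examples
#' g <- build_grid(spectrometer_spec(790, 40, 0.05, 960))
#' range(g$wavelength_nm)
build_grid <- function(spec, dialect = c("wavenumber", "wavelength")) {
  stopifnot(inherits(spec, "spectrometer_spec"))
  dialect <- match.arg(dialect)
  lam_lo <- (spec$center_wavelength - spec$bandwidth / 2) * 1e-9
  lam_hi <- (spec$center_wavelength + spec$bandwidth / 2) * 1e-9
  n <- spec$n_pixels
  if (dialect == "wavelength") {
    lambda <- seq(lam_lo, lam_hi, length.out = n)
  } else {
    # linear in k between the band-edge wavenumbers, reported in
    # increasing-wavelength order
    k_axis <- seq(2 * pi / lam_hi, 2 * pi / lam_lo, length.out = n)
    lambda <- 2 * pi / rev(k_axis)
  }
  out <- tibble(
    pixel = seq_len(n),
    wavelength_nm = lambda * 1e9,
    omega = 2 * pi * .c0 / lambda,
    k = 2 * pi / lambda
  )
  structure(out, class = c("spectral_grid", class(out)),
            spec = spec, dialect = dialect)
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %d pixels, linear in %s, %.1f-%.1f nm\n",
              nrow(x), attr(x, "dialect"),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  NextMethod()
}

grid_dialect <- function(grid) attr(grid, "dialect")

#' Centre angular frequency of a grid or spec
#'
#' `2*pi*c / center_wavelength`, the default expansion centre of the
#' dispersion phase.
#'
#' @param x A `spectral_grid` or `spectrometer_spec`.
#' @return Angular frequency in rad/s.
#' @export
center_omega <- function(x) {
  if (inherits(x, "spectral_grid")) x <- attr(x, "spec")
  stopifnot(inherits(x, "spectrometer_spec"))
  2 * pi * .c0 / (x$center_wavelength * 1e-9)
}

#' Depth-bin size of a grid
#'
#' The axial extent of one DFT depth bin for an interferogram sampled on
#' this grid: `pi / (N * dk)` where `dk` is the wavenumber pixel pitch
#' (the fringe `cos(2 k z)` of a reflector at depth `z` completes `m`
#' cycles across the sampled band when `z = m * bin size`). For a
#' wavelength-linear grid the mean pitch is used; resample to linear
#' wavenumber first for exact bin registration.
#'
#' @param grid A `spectral_grid`.
#' @return Bin size in metres.
#' @export
#' @examples
#' depth_bin_size(build_grid(spectrometer_spec()))
depth_bin_size <- function(grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  dk <- abs(mean(diff(grid$k)))
  pi / (nrow(grid) * dk)
}

#' Dispersion specification
#'
#' Coefficients of the deliberately introduced dispersion phase
#' `phi(omega) = a2*(omega - omega0)^2 + a3*(omega - omega0)^3`, the
#' encoding that broadens conjugate images while matched numerical
#' compensation keeps true structure sharp. The coefficients are in
#' seconds^2 and seconds^3 applied to the angular optical frequency
#' detuning (group-delay-dispersion scale: `a2 = 7680e-30` s^2 is 7680
#' fs^2); this interpretation yields the order-10-rad band-edge phase the
#' encoding requires and is recorded here as the package convention.
#' Defaults are the coefficients of the mirror imaging experiment.
#'
#' @param a2 Second-order coefficient, s^2. Zero allowed.
#' @param a3 Third-order coefficient, s^3. Zero allowed.
#' @param omega0 Expansion centre, rad/s. Default is the 790 nm centre
#'   frequency; pass `center_omega(grid)` to match another grid.
#' @return An object of class `dispersion_spec`.
#' @export
#' @examples
#' dispersion_spec()                      # mirror-experiment coefficients
#' dispersion_spec(0, 0)                  # dispersion-free
dispersion_spec <- function(a2 = 7680e-30, a3 = 376e-45,
                            omega0 = 2 * pi * .c0 / 790e-9) {
  stopifnot(length(a2) == 1, length(a3) == 1, length(omega0) == 1)
  if (!is.finite(a2) || !is.finite(a3)) abort("a2 and a3 must be finite")
  if (!is.finite(omega0) || omega0 <= 0) abort("omega0 must be positive")
  structure(list(a2 = a2, a3 = a3, omega0 = omega0),
            class = "dispersion_spec")
}

#' @export
print.dispersion_spec <- function(x, ...) {
  cat(sprintf("<dispersion_spec> a2 = %g s^2, a3 = %g s^3, omega0 = %g rad/s\n",
              x$a2, x$a3, x$omega0))
  invisible(x)
}

#' Dispersion coefficient presets
#'
#' The per-experiment dispersion-compensation coefficients of the system
#' this package models, as a tibble. `a2` in s^2, `a3` in s^3.
#'
#' @return A tibble with columns `experiment`, `a2`, `a3`.
#' @export
dispersion_presets <- function() {
  tibble(
    experiment = c("mirror", "fish_fin", "fish_eye", "onion"),
    a2 = c(7680e-30, 9650e-30, 10660e-30, 9377e-30),
    a3 = c(376e-45, 778e-45, 428e-45, 298e-45)
  )
}

#' Evaluate the dispersion-encoding phase on a grid
#'
#' `phi_i = a2*(omega_i - omega0)^2 + a3*(omega_i - omega0)^3` per pixel.
#'
#' @param grid A `spectral_grid`.
#' @param disp A [dispersion_spec()].
#' @return A numeric vector of phases (rad), one per pixel.
#' @export
#' @examples
#' g <- build_grid(spectrometer_spec())
#' phi <- dispersion_phase(g, dispersion_spec())
#' range(phi)   # tens of radians at the band edge
dispersion_phase <- function(grid, disp) {
  stopifnot(inherits(grid, "spectral_grid"), inherits(disp, "dispersion_spec"))
  dw <- grid$omega - disp$omega0
  disp$a2 * dw^2 + disp$a3 * dw^3
}

#' Resample a spectrum to a linear-wavenumber grid
#'
#' Measured frames come off a grating spectrometer sampled linearly in
#' wavelength; the depth transform wants samples linear in wavenumber.
#' Cubic-spline interpolates the spectrum onto a uniform-k grid with the
#' same endpoints and pixel count. Already-linear-k input passes through
#' unchanged.
#'
#' @param spectrum Real vector, one value per grid pixel.
#' @param grid A `spectral_grid` (any dialect; must be strictly monotone).
#' @return A list with elements `spectrum` (resampled values) and `grid`
#'   (the matching linear-k `spectral_grid`).
#' @export
resample_to_linear_k <- function(spectrum, grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  if (length(spectrum) != nrow(grid)) {
    abort("spectrum length must match the grid pixel count")
  }
  dl <- diff(grid$wavelength_nm)
  if (!(all(dl > 0) || all(dl < 0))) abort("grid axis must be strictly monotone")
  spec <- attr(grid, "spec")
  k_new_grid <- build_grid(spec, dialect = "wavenumber")
  if (grid_dialect(grid) == "wavenumber") {
    return(list(spectrum = spectrum, grid = k_new_grid))
  }
  ord <- order(grid$k)
  fit <- spline(x = grid$k[ord], y = spectrum[ord],
                xout = k_new_grid$k, method = "fmm")
  list(spectrum = fit$y, grid = k_new_grid)
}
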