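#' Reconstruction configuration
#'
#' Tuning parameters of the two-step compressive dispersion-encoding
#' (TCDE) reconstruction. The iteration-1 threshold is a fraction `alpha`
#' of the global peak of the compensated transform (it extracts the
#' strong reflectors); later iterations threshold at `beta` times a
#' robust noise scale (median absolute deviation of the transform
#' magnitudes) so the weak reflectors emerge once the strong ones and
#' their artifacts have been subtracted. A floor of `floor_fraction`
#' times the iteration-1 global peak keeps numerically empty residuals
#' from yielding spurious components.
#'
#' @param n_iterations Number of extraction iterations (default 2: strong
#'   components first, weak components second).
#' @param alpha Iteration-1 threshold as a fraction of the global peak
#'   magnitude, in (0, 1).
#' @param beta Later-iteration threshold multiple of the robust noise
#'   scale (> 0).
#' @param w Neighborhood half-width in bins: each extracted peak is kept
#'   together with its `w` preceding and following bins.
#' @param rescale If `TRUE` (default), multiply the zero-filled transform
#'   by `N/M` — zero filling attenuates peak amplitudes by `M/N` in
#'   expectation.
#' @param max_components Cap on peaks extracted per iteration.
#' @param refine_amplitudes If `TRUE` (default), re-estimate all component
#'   amplitudes jointly by least squares against the undersampled data
#'   (robust to aliasing leakage in the raw transform values).
#' @param conjugate_window Half-width in bins of the mirror neighborhood a
#'   candidate peak is compared against: the dispersed conjugate of a
#'   strong reflector is broadened around (not exactly at) the mirror bin,
#'   so a candidate is rejected when a larger peak lives within this
#'   window of its mirror position. Ties break toward the lower bin.
#' @param floor_fraction Absolute threshold floor as a fraction of the
#'   iteration-1 global peak.
#' @param max_iterations Cap for automatic iteration extension; when
#'   greater than `n_iterations`, iterations continue while the relative
#'   residual-energy drop of the last iteration exceeds `extend_if_drop`.
#' @param extend_if_drop Relative residual-energy drop required to extend
#'   (in (0, 1)).
#' @param r_reference Reference reflectance `R` assumed by the transform
#'   normalization (match the forward config).
#' @return A `recon_config`.
#' @export
recon_config <- function(n_iterations = 2L, alpha = 0.2, beta = 3.0, w = 1L,
                         rescale = TRUE, max_components = 16L,
                         refine_amplitudes = TRUE, conjugate_window = 40L,
                         floor_fraction = 0.01, max_iterations = n_iterations,
                         extend_if_drop = 0.5, r_reference = 0.5) {
  if (n_iterations < 1) abort("n_iterations must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (beta <= 0) abort("beta must be > 0")
  if (w < 0) abort("w must be >= 0")
  structure(
    list(n_iterations = as.integer(n_iterations), alpha = alpha, beta = beta,
         w = as.integer(w), rescale = isTRUE(rescale),
         max_components = max_components,
         refine_amplitudes = isTRUE(refine_amplitudes),
         conjugate_window = as.integer(conjugate_window),
         floor_fraction = floor_fraction,
         max_iterations = as.integer(max(max_iterations, n_iterations)),
         extend_if_drop = extend_if_drop, r_reference = r_reference),
    class = "recon_config"
  )
}

#' Dispersion-encoded depth transform
#'
#' Numerically compensates the dispersion phase and inverse-transforms to
#' depth: `u = IDFT( exp(-i phi) * f ) / R`. With matched `phi`, true
#' reflectors appear sharp and amplitude-true while their conjugates are
#' broadened and reduced; with `phi = 0` a real spectrum gives the usual
#' pair of equal conjugate peaks.
#'
#' @param f Real spectrum (full-length or zero-filled), length `N`.
#' @param phase Dispersion phase per pixel, length `N`.
#' @param r_reference Reference reflectance of the synthesis convention.
#' @return Complex depth vector of length `N`.
#' @export
#' @examples
#' f <- synthesize_full(sparse_reflectors(10, 1, 64), numeric(64))
#' round(Mod(de_transform(f, numeric(64)))[c(11, 55)], 6)  # conjugate pair
de_transform <- function(f, phase, r_reference = 0.5) {
  f <- as.numeric(f)
  if (length(phase) != length(f)) abort("phase and spectrum lengths differ")
  fft(exp(-1i * phase) * f, inverse = TRUE) / length(f) / r_reference
}

#' Full-sampling baseline reconstruction
#'
#' [de_transform()] applied to a complete spectrum — the reference result
#' that compressive reconstructions are compared against.
#'
#' @inheritParams de_transform
#' @return Complex depth vector of length `N`.
#' @export
reconstruct_full <- function(f, phase, r_reference = 0.5) {
  de_transform(f, phase, r_reference)
}

#' Extract sparse components from a depth transform
#'
#' Finds local maxima of `|u|` above `threshold` and keeps each together
#' with its `w` neighboring bins. Of any conjugate pair, only the side
#' whose peak dominates is kept: a candidate at bin `m` is dropped when a
#' strictly larger magnitude lies within `conjugate_window` bins of the
#' mirror bin `N - m` (the dispersed conjugate of a strong reflector is
#' broadened around its mirror position); at exact equality the lower bin
#' wins.
#'
#' @param u Complex depth vector.
#' @param threshold Magnitude threshold (> 0).
#' @param w Neighborhood half-width in bins.
#' @param conjugate_window Mirror-neighborhood half-width in bins.
#' @param max_components Cap on the number of peaks returned.
#' @param exclude_bins 0-based bins never accepted as peaks (e.g. support
#'   already extracted in earlier iterations).
#' @return A tibble with one row per kept bin: `peak_bin`, `bin` (both
#'   0-based), `amplitude` (complex, from `u`), `magnitude`.
#' @export
extract_components <- function(u, threshold, w = 1L, conjugate_window = 40L,
                               max_components = Inf, exclude_bins = integer()) {
  if (threshold <= 0) abort("threshold must be > 0")
  n <- length(u)
  mag <- Mod(u)
  left <- mag[c(n, seq_len(n - 1))]
  right <- mag[c(seq_len(n - 1) + 1, 1)]
  is_peak <- mag > threshold & mag >= left & mag > right  # circular; plateau ties to the lower bin
  if (length(exclude_bins)) is_peak[(exclude_bins %% n) + 1L] <- FALSE
  cand <- which(is_peak)
  if (!length(cand)) {
    return(tibble(peak_bin = integer(), bin = integer(),
                  amplitude = complex(), magnitude = numeric()))
  }
  cand <- cand[order(mag[cand], decreasing = TRUE)]
  keep <- integer()
  for (i in cand) {
    b <- i - 1L                                  # 0-based
    mir <- (n - b) %% n                          # mirror bin, 0-based
    win <- ((mir - conjugate_window):(mir + conjugate_window)) %% n + 1L
    win <- setdiff(win, i)
    mx <- if (length(win)) max(mag[win]) else 0
    if (mx > mag[i]) next
    if (mx == mag[i]) {
      # exact tie: keep the lower bin of the pair
      j <- win[which.max(mag[win])]
      if ((j - 1L) < b) next
    }
    # skip candidates inside the neighborhood of an already-kept peak
    if (length(keep) && any(pmin(abs(b - keep), n - abs(b - keep)) <= w)) next
    keep <- c(keep, b)
    if (length(keep) >= max_components) break
  }
  if (!length(keep)) {
    return(tibble(peak_bin = integer(), bin = integer(),
                  amplitude = complex(), magnitude = numeric()))
  }
  purrr::map_dfr(sort(keep), function(b) {
    bins <- ((b - w):(b + w)) %% n
    tibble(peak_bin = b, bin = as.integer(bins),
           amplitude = u[bins + 1L], magnitude = mag[bins + 1L])
  })
}

## Joint least-squares re-estimate of all component amplitudes against
## the undersampled data.
refit_amplitudes <- function(comps, f_u, phase, mask, r_reference) {
  bins <- sort(unique(comps$bin))
  A <- forward_design(bins, phase, mask, r_reference)
  fit <- lm.fit(A, as.numeric(f_u))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  k <- length(bins)
  amp <- complex(real = co[seq_len(k)], imaginary = co[k + seq_len(k)])
  comps$amplitude <- amp[match(comps$bin, bins)]
  comps$magnitude <- Mod(comps$amplitude)
  comps
}

## Real M x 2K design matrix of the masked forward operator restricted to
## `bins` (0-based): columns are the response to unit real and unit
## imaginary amplitudes at each bin.
forward_design <- function(bins, phase, mask, r_reference) {
  n <- mask$n
  i0 <- mask$indices - 1L                       # 0-based pixel indices
  theta <- outer(i0, bins, function(i, b) phase[i + 1L] - 2 * pi * i * b / n)
  cbind(2 * r_reference * cos(theta), -2 * r_reference * sin(theta))
}

#' Predict the undersampled spectrum of a component list
#'
#' Re-synthesizes the real interferogram of the extracted components
#' through the forward operator (dispersion phase, real part, sampling
#' mask) — the model subtracted from the residual to remove each
#' component together with its conjugate image and aliasing artifacts.
#'
#' @param components Tibble with columns `bin` (0-based) and `amplitude`
#'   (complex), as returned by [extract_components()].
#' @param phase Dispersion phase per pixel, length `mask$n`.
#' @param mask A [make_mask()] mask.
#' @param r_reference Reference reflectance of the synthesis convention.
#' @return Numeric vector of length `mask$m`.
#' @export
predict_spectrum <- function(components, phase, mask, r_reference = 0.5) {
  stopifnot(inherits(mask, "sampling_mask"))
  if (is.null(components) || nrow(components) == 0) return(numeric(mask$m))
  if (min(components$bin) < 0 || max(components$bin) >= mask$n) {
    abort("component bins must lie in [0, N)")
  }
  u <- complex(length.out = mask$n)
  u[components$bin + 1L] <- u[components$bin + 1L] + components$amplitude
  f <- 2 * r_reference * Re(exp(1i * phase) * fft(u))
  f[mask$indices]
}

#' Two-step compressive dispersion-encoded reconstruction (TCDE)
#'
#' Recovers the full-range sparse depth signal from a randomly
#' undersampled dispersed interferogram. Each iteration zero-fills the
#' current residual, applies the compensated depth transform (rescaled by
#' `N/M`), extracts the dominant peaks above the iteration's threshold
#' (with their neighbors, conjugates suppressed), re-estimates all
#' component amplitudes by least squares against the data, and subtracts
#' the components' predicted spectrum — removing their conjugate images
#' and incoherent aliasing artifacts — before the next iteration hunts
#' for weaker structure. Two iterations (strong then weak reflectors)
#' are the default.
#'
#' @param f_u Undersampled spectrum, length `mask$m` (an [apply_mask()]
#'   output; pass a full spectrum with a rate-1 mask for the baseline).
#' @param mask The [make_mask()] mask that produced `f_u`.
#' @param phase Dispersion phase per pixel, length `mask$n`.
#' @param cfg A [recon_config()].
#' @return A `tcde_recon` object: `u_hat` (complex length-`N` estimate,
#'   nonzero only on the extracted support), `components` (tibble with
#'   `iteration`, `peak_bin`, `bin`, `amplitude`, `magnitude`),
#'   `residual` (length `M`), `residual_energy` (per-iteration trace,
#'   starting at the input energy), `converged`/`empty` flags, `mask`,
#'   `config`.
#' @export
#' @examples
#' grid <- build_grid(spectrometer_spec(790, 40, 0.05, 1024))
#' phi <- dispersion_phase(grid, dispersion_spec())
#' f <- synthesize_full(sparse_reflectors(c(200, 250, 580), c(3, 1, 0.1), 1024), phi)
#' mk <- make_mask(1024, 0.5, seed = 2)
#' rec <- tcde(apply_mask(f, mk), mk, phi)
#' tidy(rec)
tcde <- function(f_u, mask, phase, cfg = recon_config()) {
  stopifnot(inherits(mask, "sampling_mask"), inherits(cfg, "recon_config"))
  if (length(f_u) != mask$m) abort("f_u length must equal the mask size M")
  if (length(phase) != mask$n) abort("phase length must equal the mask total N")
  n <- mask$n
  residual <- as.numeric(f_u)
  energy0 <- sum(residual^2)
  res_energy <- energy0
  comps <- NULL
  peak1 <- NA_real_
  it <- 0L
  empty <- FALSE
  while (it < cfg$max_iterations) {
    it <- it + 1L
    comps_prev <- comps
    z <- zero_fill(residual, mask)
    u_t <- de_transform(z, phase, cfg$r_reference)
    if (cfg$rescale) u_t <- u_t * n / mask$m
    mag <- Mod(u_t)
    if (it == 1L) {
      peak1 <- max(mag)
      if (peak1 == 0) { empty <- TRUE; break }
      thr <- cfg$alpha * peak1
    } else {
      thr <- max(cfg$beta * mad(mag), cfg$floor_fraction * peak1)
      if (thr <= 0) break
    }
    excl <- if (is.null(comps)) integer() else unique(comps$bin)
    # keep the amplitude fit overdetermined: each peak costs 2*(2w+1) real
    # parameters, and we require at least twice as many equations
    n_have <- if (is.null(comps)) 0L else length(unique(comps$peak_bin))
    budget <- floor(mask$m / (4 * (2 * cfg$w + 1))) - n_have
    if (budget < 1) break
    new <- extract_components(u_t, thr, w = cfg$w,
                              conjugate_window = cfg$conjugate_window,
                              max_components = min(cfg$max_components, budget),
                              exclude_bins = excl)
    if (nrow(new) == 0) {
      if (it == 1L) empty <- TRUE
      break
    }
    new <- dplyr::filter(new, !(bin %in% excl))
    new$iteration <- it
    comps <- bind_rows(comps, new)
    if (cfg$refine_amplitudes) {
      comps <- refit_amplitudes(comps, f_u, phase, mask, cfg$r_reference)
      # prune peaks whose refit centre magnitude collapsed below the floor
      # (aliasing artifacts fully explained by the other components)
      ctr <- comps[comps$bin == comps$peak_bin, ]
      bad <- ctr$peak_bin[ctr$magnitude < cfg$floor_fraction * peak1]
      if (length(bad)) {
        comps <- dplyr::filter(comps, !(peak_bin %in% bad))
        if (nrow(comps) == 0) {
          comps <- NULL
          if (it == 1L) { empty <- TRUE; break }
          break
        }
        comps <- refit_amplitudes(comps, f_u, phase, mask, cfg$r_reference)
      }
    }
    fit_bins <- dplyr::distinct(comps[, c("bin", "amplitude")], bin, .keep_all = TRUE)
    new_residual <- as.numeric(f_u) - predict_spectrum(fit_bins, phase, mask, cfg$r_reference)
    new_energy <- sum(new_residual^2)
    if (new_energy > res_energy[length(res_energy)] * (1 + 1e-12)) {
      # subtracting this iteration's model would increase the residual:
      # roll back and stop
      comps <- comps_prev
      break
    }
    residual <- new_residual
    res_energy <- c(res_energy, new_energy)
    if (it >= cfg$n_iterations && it < cfg$max_iterations) {
      drop <- 1 - res_energy[length(res_energy)] /
        max(res_energy[length(res_energy) - 1], .Machine$double.eps)
      if (drop <= cfg$extend_if_drop) break
    }
  }
  if (is.null(comps)) {
    comps <- tibble(iteration = integer(), peak_bin = integer(),
                    bin = integer(), amplitude = complex(),
                    magnitude = numeric())
    empty <- TRUE
  }
  u_hat <- complex(length.out = n)
  fit_bins <- dplyr::distinct(comps[, c("bin", "amplitude")], bin, .keep_all = TRUE)
  if (nrow(fit_bins)) u_hat[fit_bins$bin + 1L] <- fit_bins$amplitude
  structure(
    list(u_hat = u_hat,
         components = comps[, c("iteration", "peak_bin", "bin", "amplitude",
                                "magnitude")],
         residual = residual, residual_energy = res_energy,
         iterations = it, empty = empty, mask = mask, config = cfg),
    class = "tcde_recon"
  )
}

#' @export
print.tcde_recon <- function(x, ...) {
  cat(sprintf(
    "<tcde_recon> N = %d, rate %.2f, %d iterations, %d peaks%s\n",
    x$mask$n, x$mask$rate, x$iterations,
    length(unique(x$components$peak_bin)),
    if (x$empty) " (empty: no component found)" else ""))
  cat(" residual energy:", format(x$residual_energy, digits = 4), "\n")
  invisible(x)
}

#' Tidy a TCDE reconstruction
#'
#' One row per extracted peak, with its least-squares amplitude.
#'
#' @param x A `tcde_recon`.
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `bin` (0-based peak bin),
#'   `amplitude` (complex), `magnitude`, `phase_rad`.
#' @method tidy tcde_recon
#' @export
tidy.tcde_recon <- function(x, ...) {
  peaks <- dplyr::filter(x$components, bin == peak_bin)
  tibble(iteration = peaks$iteration, bin = peaks$peak_bin,
         amplitude = peaks$amplitude, magnitude = peaks$magnitude,
         phase_rad = Arg(peaks$amplitude))
}

#' Glance at a TCDE reconstruction
#'
#' @param x A `tcde_recon`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `m`, `rate`, `iterations`, `n_peaks`,
#'   `initial_energy`, `final_energy`, `empty`.
#' @method glance tcde_recon
#' @export
glance.tcde_recon <- function(x, ...) {
  tibble(n = x$mask$n, m = x$mask$m, rate = x$mask$rate,
         iterations = x$iterations,
         n_peaks = length(unique(x$components$peak_bin)),
         initial_energy = x$residual_energy[1],
         final_energy = x$residual_energy[length(x$residual_energy)],
         empty = x$empty)
}
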