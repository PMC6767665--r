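#' Forward-model configuration
#'
#' Parameters of the interferogram synthesis: the reference-arm
#' reflectance `R`, the pre-introduced channel offset `d` (in depth bins),
#' and the detection-noise model. The amplitude convention is fixed so
#' that the full pipeline is amplitude-preserving: with the default
#' `r_reference = 0.5` the factor `2R` is 1 and a matched, fully sampled
#' reconstruction returns component magnitudes equal to the input `|S|`.
#'
#' @param r_reference Reference-arm reflectance `R` (> 0).
#' @param d_bins Channel offset `d` in depth bins; the two channels'
#'   signals are separated by `2 d` bins. Must satisfy `0 < d <= N/2`.
#' @param include_autocorrelation If `TRUE`, add the DC/autocorrelation
#'   term `R^2 + sum |S|^2` per pixel (off by default; real systems
#'   subtract the reference background).
#' @param noise_sd Additive Gaussian noise sigma, counts (0 = off).
#' @param shot_noise If `TRUE`, apply Poisson shot noise to
#'   offset-shifted counts.
#' @param shot_offset Counts added before Poisson resampling (keeps the
#'   rate positive); subtracted again afterwards.
#' @param seed Noise RNG seed.
#' @return A `forward_config`.
#' @export
forward_config <- function(r_reference = 0.5, d_bins = NULL,
                           include_autocorrelation = FALSE,
                           noise_sd = 0, shot_noise = FALSE,
                           shot_offset = 100, seed = 1L) {
  if (r_reference <= 0) abort("r_reference must be > 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(
    list(r_reference = r_reference, d_bins = d_bins,
         include_autocorrelation = include_autocorrelation,
         noise_sd = noise_sd, shot_noise = shot_noise,
         shot_offset = shot_offset, seed = seed),
    class = "forward_config"
  )
}

#' Embed two channel profiles into one full-range vector
#'
#' Channel 1 images optical paths `[0, 2d)` and channel 2 images
#' `(-2d, 0]`; because the detected spectrum is real, negative depths
#' live in the upper half of the length-`N` DFT vector (depth `-j` at
#' index `N - j`). Channel-1 bin `c` maps to index `c`; channel-2 bin
#' `c` (depth `-c`) maps to index `(N - c) mod N`. Index 0 — the shared
#' zero-path bin — is attributed to channel 1.
#'
#' @param S1,S2 `depth_profile`s (or complex vectors), each at most `2 d`
#'   bins long, bin 0 at the channel's zero-path reference.
#' @param d Channel offset in bins.
#' @param n Full-range vector length `N` (spectrometer pixel count).
#' @return Complex vector `u` of length `n`.
#' @export
#' @examples
#' u <- embed_full_range(mirror_phantom(5, 1, 32), NULL, d = 64, n = 256)
#' which(Mod(u) > 0) - 1
embed_full_range <- function(S1, S2, d, n) {
  n <- as.integer(n)
  if (is.null(d) || d <= 0 || d > n / 2) abort("need 0 < d <= N/2 bins")
  u <- complex(length.out = n)
  if (!is.null(S1) && length(S1)) {
    if (length(S1) > 2 * d) abort("channel-1 profile longer than 2d bins (channel overlap)")
    a <- as.complex(unclass(S1))
    u[seq_along(a)] <- u[seq_along(a)] + a
  }
  if (!is.null(S2) && length(S2)) {
    if (length(S2) > 2 * d) abort("channel-2 profile longer than 2d bins (channel overlap)")
    a <- as.complex(unclass(S2))
    idx <- (n - (seq_along(a) - 1L)) %% n + 1L   # depth -c at index N - c
    for (t in seq_along(a)) u[idx[t]] <- u[idx[t]] + a[t]
  }
  u
}

#' Synthesize the interferogram of a full-range vector
#'
#' The detected spectrum is `f = 2R * Re[ exp(i phi) * DFT(u) ]` (plus the
#' optional autocorrelation background): the dispersion phase is applied
#' in the spectral domain, and taking the real part is what folds the two
#' depth half-spaces into one real spectrum and creates the conjugate
#' ambiguity the dispersion encoding resolves.
#'
#' @param u Complex full-range vector, length `N`.
#' @param phase Dispersion phase per pixel (rad), length `N`.
#' @param cfg A [forward_config()].
#' @return An `interferogram`: numeric vector of length `N` with the
#'   config attached as an attribute.
#' @export
synthesize_full <- function(u, phase, cfg = forward_config()) {
  u <- as.complex(unclass(u))
  if (length(phase) != length(u)) abort("phase and u must have the same length")
  f <- 2 * cfg$r_reference * Re(exp(1i * phase) * fft(u))
  if (isTRUE(cfg$include_autocorrelation)) {
    f <- f + cfg$r_reference^2 + sum(Mod(u)^2)
  }
  structure(f, class = "interferogram", config = cfg)
}

#' Synthesize the dual-channel interferogram of a scene pair
#'
#' Embeds the two channel profiles at the configured offset `d` and calls
#' [synthesize_full()]. Noise, if configured, is added via [add_noise()].
#'
#' @param S1,S2 Channel depth profiles (bin 0 at each channel's
#'   zero-path reference).
#' @param phase Dispersion phase per pixel, length `N`.
#' @param cfg A [forward_config()] with `d_bins` set.
#' @param n Spectrometer pixel count `N` (defaults to `length(phase)`).
#' @return An `interferogram` of length `n`.
#' @export
#' @examples
#' phi <- numeric(256)
#' f <- synthesize(mirror_phantom(10, 1, 64), NULL, phi,
#'                 forward_config(d_bins = 64))
synthesize <- function(S1, S2, phase, cfg = forward_config(), n = length(phase)) {
  u <- embed_full_range(S1, S2, d = cfg$d_bins, n = n)
  f <- synthesize_full(u, phase, cfg)
  if (cfg$noise_sd > 0 || isTRUE(cfg$shot_noise)) f <- add_noise(f, cfg)
  f
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram> %d pixels, range [%.3g, %.3g]\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' @rdname synthesize_full
#' @param x An `interferogram`.
#' @param ... Unused.
#' @method tidy interferogram
#' @export
tidy.interferogram <- function(x, ...) {
  tibble(pixel = seq_along(x), counts = as.numeric(x))
}

#' Add detection noise to an interferogram
#'
#' Additive zero-mean Gaussian noise and/or Poisson shot noise on
#' offset-shifted counts. Reproducible: the same `cfg$seed` gives the
#' same noise realization.
#'
#' @param f An `interferogram` (or numeric spectrum).
#' @param cfg A [forward_config()] carrying `noise_sd`, `shot_noise`,
#'   `shot_offset` and `seed`.
#' @return A noisy `interferogram` of the same length.
#' @export
add_noise <- function(f, cfg) {
  y <- as.numeric(f)
  y <- local_seed(cfg$seed, {
    if (isTRUE(cfg$shot_noise)) {
      rate <- pmax(y + cfg$shot_offset, 0)
      y <- rpois(length(y), rate) - cfg$shot_offset
    }
    if (cfg$noise_sd > 0) y <- y + rnorm(length(y), sd = cfg$noise_sd)
    y
  })
  structure(y, class = "interferogram", config = cfg)
}

#' Simulate the interferogram stack of a B-scan
#'
#' Applies [synthesize()] at every lateral position of a scene, in order.
#' Per-A-line noise seeds are derived from `cfg$seed` so that lateral
#' positions get independent, reproducible noise.
#'
#' @param scene A [two_channel_scene()].
#' @param phase Dispersion phase per pixel.
#' @param cfg A [forward_config()] with `d_bins` set.
#' @return A list of `interferogram`s, one per lateral position.
#' @export
simulate_bscan <- function(scene, phase, cfg = forward_config()) {
  stopifnot(inherits(scene, "scene"))
  lapply(seq_along(scene$pairs), function(m) {
    cfg_m <- cfg
    cfg_m$seed <- (cfg$seed %||% 1L) + m - 1L
    synthesize(scene$pairs[[m]]$S1, scene$pairs[[m]]$S2, phase, cfg_m)
  })
}
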