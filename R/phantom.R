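#' Depth profiles
#'
#' A depth profile is the complex backscatter amplitude `S_j` of one
#' channel on an integer depth-bin grid `j = 0 ... n-1`, bin 0 at the
#' channel's zero-path reference. Constructed by the phantom generators
#' below; stored as a complex vector of class `depth_profile` with the
#' channel label and (optionally) the generating seed as attributes.
#'
#' @param amplitude Complex (or numeric) vector of per-bin amplitudes.
#' @param channel Optional channel label (1 or 2).
#' @param seed Optional RNG seed recorded for provenance.
#' @return A `depth_profile`.
#' @export
depth_profile <- function(amplitude, channel = NA_integer_, seed = NULL) {
  if (!all(is.finite(Re(amplitude))) || !all(is.finite(Im(as.complex(amplitude))))) {
    abort("depth_profile amplitudes must be finite")
  }
  structure(as.complex(amplitude), class = "depth_profile",
            channel = channel, seed = seed)
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %d bins, %d nonzero, channel %s\n",
              length(x), sum(Mod(unclass(x)) > 0), as.character(attr(x, "channel"))))
  invisible(x)
}

#' @rdname depth_profile
#' @param x A `depth_profile`.
#' @param ... Unused.
#' @method tidy depth_profile
#' @export
tidy.depth_profile <- function(x, ...) {
  a <- unclass(x)
  tibble(bin = seq_along(a) - 1L, amplitude = a, magnitude = Mod(a))
}

#' Sparse-reflector phantom
#'
#' A depth profile that is zero except at a handful of reflector bins —
#' the sparse structure the compressive reconstruction assumes. The
#' canonical simulation signal of this package is
#' `sparse_reflectors(c(200, 250, 580), c(3, 1, 0.1), 1024)`.
#'
#' @param indices Integer depth bins (0-based), distinct, in `[0, n)`.
#' @param amplitudes Amplitudes (complex allowed), one per index.
#' @param n Profile length in bins.
#' @param channel Optional channel label.
#' @return A `depth_profile` with `length(indices)` nonzeros.
#' @export
#' @examples
#' p <- sparse_reflectors(c(200, 250, 580), c(3, 1, 0.1), 1024)
#' sum(Mod(p) > 0)
sparse_reflectors <- function(indices, amplitudes, n, channel = NA_integer_) {
  stopifnot(length(indices) == length(amplitudes), n >= 1)
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) abort("reflector indices must be distinct")
  if (length(indices) && (min(indices) < 0 || max(indices) >= n)) {
    abort(sprintf("reflector indices must lie in [0, %d)", as.integer(n)))
  }
  a <- complex(length.out = n)
  a[indices + 1L] <- as.complex(amplitudes)
  depth_profile(a, channel = channel)
}

#' Single-mirror phantom
#'
#' One reflector at one depth bin — the phantom used for sensitivity and
#' sampling-rate experiments.
#'
#' @param depth_bin Depth bin of the mirror (0-based).
#' @param amplitude Reflector amplitude.
#' @param n Profile length in bins.
#' @param channel Optional channel label.
#' @return A `depth_profile`.
#' @export
mirror_phantom <- function(depth_bin, amplitude, n, channel = NA_integer_) {
  if (amplitude == 0) return(sparse_reflectors(integer(), numeric(), n, channel))
  sparse_reflectors(depth_bin, amplitude, n, channel)
}

#' Layered scattering phantom with speckle
#'
#' A synthetic stand-in for layered tissue: discrete layers whose
#' amplitude decays exponentially with depth, optionally textured with
#' circular complex Gaussian speckle (the standard fully developed
#' speckle model). Deterministic given `seed`.
#'
#' @param layer_bins Integer depth bins of the layers (0-based).
#' @param layer_amp Amplitude of each layer before attenuation.
#' @param speckle_fraction Relative speckle strength in `[0, 1]`: each
#'   layer amplitude is multiplied by `(1 - speckle_fraction) +
#'   speckle_fraction * g` with `g` a unit circular complex Gaussian.
#' @param attenuation_per_bin Exponential amplitude decay rate per bin
#'   (>= 0); layer at bin `j` is scaled by `exp(-attenuation_per_bin * j)`.
#' @param seed RNG seed; recorded on the profile.
#' @param n Profile length in bins.
#' @param channel Optional channel label.
#' @return A `depth_profile`.
#' @export
#' @examples
#' p <- layered_phantom(c(30, 60, 90), c(1, 1, 1), 0.3, 0.01, seed = 1, n = 256)
layered_phantom <- function(layer_bins, layer_amp, speckle_fraction = 0,
                            attenuation_per_bin = 0, seed = 1L, n,
                            channel = NA_integer_) {
  stopifnot(length(layer_bins) == length(layer_amp))
  if (speckle_fraction < 0 || speckle_fraction > 1) {
    abort("speckle_fraction must be in [0, 1]")
  }
  if (attenuation_per_bin < 0) abort("attenuation_per_bin must be >= 0")
  layer_bins <- as.integer(layer_bins)
  if (length(layer_bins) && (min(layer_bins) < 0 || max(layer_bins) >= n)) {
    abort(sprintf("layer bins must lie in [0, %d)", as.integer(n)))
  }
  base <- layer_amp * exp(-attenuation_per_bin * layer_bins)
  amp <- local_seed(seed, {
    g <- complex(real = rnorm(length(layer_bins), sd = sqrt(0.5)),
                 imaginary = rnorm(length(layer_bins), sd = sqrt(0.5)))
    base * ((1 - speckle_fraction) + speckle_fraction * g)
  })
  a <- complex(length.out = n)
  a[layer_bins + 1L] <- amp
  depth_profile(a, channel = channel, seed = seed)
}

#' Apply a confocal amplitude window to a depth profile
#'
#' A simple Gaussian amplitude envelope centred on the focal bin,
#' modelling suppression of backscatter away from the depth of focus.
#' Never increases `|S|` at any bin.
#'
#' @param profile A `depth_profile`.
#' @param focal_bin Centre of the window (0-based bin).
#' @param width_bins 1/e half-width of the amplitude envelope, in bins.
#' @return A `depth_profile` of the same length.
#' @export
confocal_window <- function(profile, focal_bin, width_bins) {
  stopifnot(inherits(profile, "depth_profile"), width_bins > 0)
  j <- seq_along(profile) - 1L
  w <- exp(-((j - focal_bin) / width_bins)^2)
  depth_profile(unclass(profile) * w, channel = attr(profile, "channel"),
                seed = attr(profile, "seed"))
}

#' Two-channel scene
#'
#' Lays a phantom object out over the two channels of the dual-channel
#' system as a sequence of lateral positions.
#'
#' In mode 1 (speed mode) the two sample beams scan laterally adjacent
#' regions of the *same* depth range: the object — a complex matrix of
#' `n_ch` depth bins by `2 * n_lateral` lateral positions — is split left
#' (channel 1) / right (channel 2).
#'
#' In mode 2 (depth mode) the beams are focused at stacked depths: the
#' object has `2 * n_ch` depth bins by `n_lateral` positions; channel 1
#' images its upper half and channel 2 the lower half, one full depth
#' range deeper, with an optional lateral offset between the two beams
#' (positive: channel 2 lags channel 1 by that many positions, as when
#' the two beams scan the sample simultaneously side by side).
#'
#' @param mode Imaging mode, 1 or 2.
#' @param object Complex matrix (depth bins x lateral positions); see
#'   Details for the required shape per mode.
#' @param n_ch Per-channel depth range in bins (rows of each profile).
#' @param lateral_offset_px Mode-2 lateral offset of channel 2, in pixels.
#' @param lateral_pitch_m Lateral spacing between A-scans, metres.
#' @param seed Optional seed recorded in the scene metadata.
#' @return A `scene`: list with `mode`, `pairs` (list of `list(S1, S2)`
#'   depth profiles), `n_lateral`, `lateral_pitch_m`, `lateral_offset_px`,
#'   `seed`.
#' @export
#' @examples
#' obj <- matrix(0+0i, nrow = 64, ncol = 4)
#' obj[10, ] <- 1; obj[50, ] <- 0.5
#' sc <- two_channel_scene(2, obj, n_ch = 32)
#' length(sc$pairs)
two_channel_scene <- function(mode, object, n_ch, lateral_offset_px = 0L,
                              lateral_pitch_m = 10e-6, seed = NULL) {
  if (!mode %in% c(1L, 2L)) abort("mode must be 1 or 2")
  stopifnot(is.matrix(object))
  object <- matrix(as.complex(object), nrow = nrow(object))
  if (mode == 1) {
    if (nrow(object) != n_ch) abort("mode 1 object must have n_ch rows")
    if (ncol(object) %% 2 != 0) abort("mode 1 object needs an even number of columns")
    n_lat <- ncol(object) %/% 2
    pairs <- lapply(seq_len(n_lat), function(m) {
      list(S1 = depth_profile(object[, m], channel = 1L),
           S2 = depth_profile(object[, n_lat + m], channel = 2L))
    })
  } else {
    if (nrow(object) != 2 * n_ch) abort("mode 2 object must have 2 * n_ch rows")
    n_lat <- ncol(object)
    off <- as.integer(lateral_offset_px)
    pairs <- lapply(seq_len(n_lat), function(m) {
      m2 <- m - off
      s2 <- if (m2 >= 1 && m2 <= n_lat) object[n_ch + seq_len(n_ch), m2] else
        complex(length.out = n_ch)
      list(S1 = depth_profile(object[seq_len(n_ch), m], channel = 1L),
           S2 = depth_profile(s2, channel = 2L))
    })
  }
  structure(
    list(mode = as.integer(mode), pairs = pairs, n_lateral = length(pairs),
         lateral_pitch_m = lateral_pitch_m,
         lateral_offset_px = as.integer(lateral_offset_px), seed = seed),
    class = "scene"
  )
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> mode %d, %d lateral positions, %d bins per channel\n",
              x$mode, x$n_lateral, length(x$pairs[[1]]$S1)))
  invisible(x)
}

## Evaluate expr under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
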