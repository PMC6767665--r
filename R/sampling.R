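#' Random spectral sampling mask
#'
#' The random row-selection operator of compressive spectral readout:
#' `M = round(rate * N)` pixel indices drawn uniformly without
#' replacement. Indices are 1-based (R convention), sorted, distinct.
#'
#' @param n Total spectrometer pixels `N`.
#' @param rate Sampling rate `M/N`, in `(0, 1]`.
#' @param seed RNG seed; the mask is reproducible from `(n, rate, seed)`.
#' @return A `sampling_mask`: list with `indices`, `n`, `m`, `rate`
#'   (realized `M/N`), `seed`.
#' @export
#' @examples
#' mk <- make_mask(1000, 0.5, seed = 7)
#' mk$m
make_mask <- function(n, rate, seed = 1L) {
  n <- as.integer(n)
  if (!is.finite(rate) || rate <= 0 || rate > 1) {
    abort("sampling rate must be in (0, 1]")
  }
  m <- max(1L, as.integer(round(rate * n)))
  idx <- if (m == n) seq_len(n) else local_seed(seed, sort(sample.int(n, m)))
  structure(list(indices = idx, n = n, m = m, rate = m / n, seed = seed),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> %d of %d pixels (rate %.3f), seed %s\n",
              x$m, x$n, x$rate, as.character(x$seed)))
  invisible(x)
}

#' Apply a sampling mask to a spectrum
#'
#' Extracts the sampled pixels: `f_u[t] = f[indices[t]]`.
#'
#' @param f Full-length spectrum (length `mask$n`).
#' @param mask A [make_mask()] mask.
#' @return Numeric vector of length `mask$m`.
#' @export
apply_mask <- function(f, mask) {
  stopifnot(inherits(mask, "sampling_mask"))
  if (length(f) != mask$n) abort("mask and spectrum lengths differ")
  as.numeric(f)[mask$indices]
}

#' Zero-fill an undersampled spectrum
#'
#' The adjoint of [apply_mask()]: sampled values return to their pixel
#' positions, every other pixel is exactly zero.
#'
#' @param f_u Undersampled values, length `mask$m`.
#' @param mask A [make_mask()] mask.
#' @return Numeric vector of length `mask$n`.
#' @export
zero_fill <- function(f_u, mask) {
  stopifnot(inherits(mask, "sampling_mask"))
  if (length(f_u) != mask$m) abort("f_u length must equal the mask size M")
  out <- numeric(mask$n)
  out[mask$indices] <- as.numeric(f_u)
  out
}

#' Serialize / restore a sampling mask as JSON
#'
#' Masks round-trip through a small JSON record `(n, rate, seed, indices)`
#' for exact replay of a reconstruction.
#'
#' @param mask A `sampling_mask`.
#' @param path File path to write to / read from.
#' @return `mask_to_json` returns `path` invisibly; `mask_from_json`
#'   returns the restored `sampling_mask`.
#' @export
mask_to_json <- function(mask, path) {
  stopifnot(inherits(mask, "sampling_mask"))
  jsonlite::write_json(
    list(n = mask$n, m = mask$m, rate = mask$rate, seed = mask$seed,
         indices = mask$indices),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mask_to_json
#' @export
mask_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(indices = as.integer(x$indices), n = as.integer(x$n),
                 m = as.integer(x$m), rate = x$rate, seed = x$seed),
            class = "sampling_mask")
}
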