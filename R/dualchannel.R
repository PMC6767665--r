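#' Channel layout of the full-range depth axis
#'
#' Bookkeeping for splitting a full-range reconstruction into its two
#' channels: channel 1 owns depth bins `[0, 2d)` (index = depth), channel
#' 2 owns negative depths `-1 ... -(2d-1)` stored at indices `N-1 ...
#' N-(2d-1)`. The shared zero-path bin 0 is attributed to channel 1, so
#' the two windows are disjoint.
#'
#' @param d_bins Channel offset `d` in bins; requires `2 d <= N/2`.
#' @param n Full-range vector length `N`.
#' @param bin_size_m Axial bin size in metres (e.g. [depth_bin_size()]);
#'   used only for reporting pitches.
#' @return A `channel_layout`.
#' @export
channel_layout <- function(d_bins, n, bin_size_m = NA_real_) {
  d_bins <- as.integer(d_bins)
  n <- as.integer(n)
  if (d_bins <= 0 || 2 * d_bins > n / 2) abort("need 0 < 2*d <= N/2 bins")
  structure(list(d_bins = d_bins, n = n, n_ch = 2L * d_bins,
                 bin_size_m = bin_size_m),
            class = "channel_layout")
}

#' @export
print.channel_layout <- function(x, ...) {
  cat(sprintf("<channel_layout> N = %d, d = %d bins, %d bins per channel\n",
              x$n, x$d_bins, x$n_ch))
  invisible(x)
}

#' Demultiplex a full-range reconstruction into the two channels
#'
#' Channel 1's A-scan is `|u|` on bins `0 ... 2d-1`. Channel 2's A-scan
#' is read from the wrapped negative-depth window and re-indexed so that
#' its bin 0 sits at the channel-2 zero path and depth increases into the
#' sample: channel-2 bin `c` is `|u[N - c]|` for `c >= 1` (bin 0, the
#' shared zero-path pixel, is attributed to channel 1 and reads 0 here).
#'
#' @param u_hat Complex (or numeric) full-range vector of length
#'   `layout$n`.
#' @param layout A [channel_layout()].
#' @return A tibble with columns `channel` (1 or 2), `bin` (0-based,
#'   depth into the sample) and `magnitude`.
#' @export
#' @examples
#' lay <- channel_layout(16, 128)
#' dm <- demux(embed_full_range(mirror_phantom(5, 1, 32),
#'                              mirror_phantom(7, 2, 32), 16, 128), lay)
#' dm[dm$magnitude > 0, ]
demux <- function(u_hat, layout) {
  stopifnot(inherits(layout, "channel_layout"))
  if (length(u_hat) != layout$n) abort("u_hat length must equal layout N")
  m <- Mod(u_hat)
  n <- layout$n
  nc <- layout$n_ch
  a1 <- m[seq_len(nc)]
  a2 <- c(0, m[n - seq_len(nc - 1L) + 1L])
  bind_rows(
    tibble(channel = 1L, bin = seq_len(nc) - 1L, magnitude = a1),
    tibble(channel = 2L, bin = seq_len(nc) - 1L, magnitude = a2)
  )
}

#' B-scan container
#'
#' A 2-D magnitude image: rows are depth bins (top = bin 0), columns are
#' lateral positions.
#'
#' @param image Non-negative numeric matrix (depth x lateral).
#' @param axial_pitch_mm,lateral_pitch_mm Pixel pitches, mm.
#' @param channel,mode Provenance tags.
#' @param scale `"linear"` or `"dB"`.
#' @return A `bscan`.
#' @export
bscan <- function(image, axial_pitch_mm = NA_real_, lateral_pitch_mm = NA_real_,
                  channel = NA_integer_, mode = NA_integer_,
                  scale = c("linear", "dB")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(image))
  if (scale == "linear" && any(image < 0)) abort("linear-scale magnitudes must be non-negative")
  structure(list(image = image, axial_pitch_mm = axial_pitch_mm,
                 lateral_pitch_mm = lateral_pitch_mm, channel = channel,
                 mode = mode, scale = scale,
                 stitched_gap_cols = integer()),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %d depth bins x %d positions (%s scale)\n",
              nrow(x$image), ncol(x$image), x$scale))
  invisible(x)
}

#' @rdname bscan
#' @param x A `bscan`.
#' @param ... Unused.
#' @method tidy bscan
#' @export
tidy.bscan <- function(x, ...) {
  img <- x$image
  tibble(
    depth_bin = rep(seq_len(nrow(img)) - 1L, times = ncol(img)),
    lateral = rep(seq_len(ncol(img)) - 1L, each = nrow(img)),
    value = as.vector(img)
  )
}

#' Assemble per-channel B-scans from reconstructions
#'
#' Demultiplexes each full-range A-scan estimate in `recons` and stacks
#' one channel's magnitudes into a B-scan.
#'
#' @param recons List of `tcde_recon` objects or complex vectors, in
#'   lateral order.
#' @param layout A [channel_layout()].
#' @param channel Which channel to assemble (1 or 2).
#' @param lateral_pitch_mm Lateral pitch, mm.
#' @return A `bscan` with `layout$n_ch` rows.
#' @export
assemble_bscan <- function(recons, layout, channel = 1L,
                           lateral_pitch_mm = NA_real_) {
  cols <- vapply(recons, function(r) {
    u <- if (inherits(r, "tcde_recon")) r$u_hat else r
    dm <- demux(u, layout)
    dm$magnitude[dm$channel == channel]
  }, numeric(layout$n_ch))
  bscan(matrix(cols, nrow = layout$n_ch),
        axial_pitch_mm = layout$bin_size_m * 1e3,
        lateral_pitch_mm = lateral_pitch_mm,
        channel = as.integer(channel))
}

#' Stitch the two channels laterally (mode 1)
#'
#' In speed mode the two beams scan laterally adjacent regions; the image
#' is the side-by-side concatenation `[channel 1 | dead zone | channel 2]`,
#' the dead zone (the unscanned gap between the two objective footprints)
#' zero-filled and flagged in `stitched_gap_cols`.
#'
#' @param b1,b2 `bscan`s with equal depth extents.
#' @param dead_zone_px Width of the dead zone, columns.
#' @return A stitched `bscan`.
#' @export
stitch_mode1 <- function(b1, b2, dead_zone_px = 0L) {
  stopifnot(inherits(b1, "bscan"), inherits(b2, "bscan"))
  if (nrow(b1$image) != nrow(b2$image)) abort("depth extents differ")
  dead_zone_px <- as.integer(dead_zone_px)
  gap <- matrix(0, nrow = nrow(b1$image), ncol = dead_zone_px)
  out <- bscan(cbind(b1$image, gap, b2$image),
               axial_pitch_mm = b1$axial_pitch_mm,
               lateral_pitch_mm = b1$lateral_pitch_mm, mode = 1L,
               scale = b1$scale)
  out$stitched_gap_cols <- ncol(b1$image) + seq_len(dead_zone_px)
  out$source_cols <- c(rep(1L, ncol(b1$image)), rep(NA_integer_, dead_zone_px),
                       rep(2L, ncol(b2$image)))
  out
}

#' Stitch the two channels axially (mode 2)
#'
#' In depth mode channel 1 images the upper structure and channel 2 the
#' structure one full depth range deeper; the stitched image places the
#' deep scan under the upper one after shifting it laterally by
#' `x_shift_px` (the instrument's beam offset). An overlap of
#' `overlap_px` rows is blended by the elementwise maximum (robust to the
#' deeper channel's lower signal level).
#'
#' @param b_upper,b_deep `bscan`s; equal widths after shift-cropping.
#' @param x_shift_px Lateral shift of the deep scan, columns
#'   (non-negative; must be smaller than the width).
#' @param overlap_px Rows shared by the bottom of the upper scan and the
#'   top of the deep scan.
#' @return A stitched `bscan` with
#'   `nrow(b_upper) + nrow(b_deep) - overlap_px` rows.
#' @export
stitch_mode2 <- function(b_upper, b_deep, x_shift_px = 0L, overlap_px = 0L) {
  stopifnot(inherits(b_upper, "bscan"), inherits(b_deep, "bscan"))
  x_shift_px <- as.integer(x_shift_px)
  overlap_px <- as.integer(overlap_px)
  wu <- ncol(b_upper$image)
  wd <- ncol(b_deep$image)
  if (x_shift_px < 0) abort("x_shift_px must be >= 0")
  if (x_shift_px >= wd || x_shift_px >= wu) abort("shift must be smaller than the scan width")
  # common lateral support after shifting the deep scan right by x_shift_px
  up <- b_upper$image[, (1 + x_shift_px):wu, drop = FALSE]
  dp <- b_deep$image[, 1:(wd - x_shift_px), drop = FALSE]
  w <- min(ncol(up), ncol(dp))
  up <- up[, seq_len(w), drop = FALSE]
  dp <- dp[, seq_len(w), drop = FALSE]
  if (overlap_px < 0 || overlap_px > min(nrow(up), nrow(dp))) {
    abort("overlap_px out of range")
  }
  if (overlap_px > 0) {
    ov <- pmax(up[nrow(up) - overlap_px + seq_len(overlap_px), , drop = FALSE],
               dp[seq_len(overlap_px), , drop = FALSE])
    img <- rbind(up[seq_len(nrow(up) - overlap_px), , drop = FALSE],
                 ov,
                 dp[(overlap_px + 1):nrow(dp), , drop = FALSE])
  } else {
    img <- rbind(up, dp)
  }
  bscan(img, axial_pitch_mm = b_upper$axial_pitch_mm,
        lateral_pitch_mm = b_upper$lateral_pitch_mm, mode = 2L,
        scale = b_upper$scale)
}

#' A-scan signal-to-noise ratio in dB
#'
#' `20 * log10( peak height / sd(noise floor) )`: twenty times the
#' base-10 logarithm of the ratio of the A-scan peak height to the
#' standard deviation of the noise floor.
#'
#' @param ascan Magnitude vector.
#' @param peak_index Index of the signal peak (0-based bin).
#' @param noise_window 0-based bins of the noise floor; must exclude the
#'   peak and contain at least 8 bins.
#' @return SNR in dB (`Inf` if the noise floor has zero spread).
#' @export
#' @examples
#' snr_db(c(rep(1, 20), 100), 20, 0:19 )  # approx 40 dB
snr_db <- function(ascan, peak_index, noise_window) {
  if (length(noise_window) < 8) abort("noise window must contain at least 8 bins")
  if (peak_index %in% noise_window) abort("noise window must exclude the peak")
  peak <- ascan[peak_index + 1L]
  ns <- sd(ascan[noise_window + 1L])
  if (ns == 0) return(Inf)
  20 * log10(peak / ns)
}

#' Map a B-scan to an 8-bit dB image
#'
#' `20*log10` of the linear magnitudes, clipped at `floor_db` below the
#' image maximum, linearly quantized to 0-255.
#'
#' @param b A linear-scale `bscan`.
#' @param floor_db Dynamic range floor in dB (positive number of dB below
#'   the maximum).
#' @return An integer matrix in 0-255.
#' @export
to_db_image <- function(b, floor_db = 40) {
  stopifnot(inherits(b, "bscan"))
  if (b$scale != "linear") abort("to_db_image expects a linear-scale bscan")
  img <- b$image
  mx <- max(img)
  if (mx <= 0) return(matrix(0L, nrow(img), ncol(img)))
  db <- 20 * log10(pmax(img, mx * 10^(-floor_db / 20 - 1)) / mx)  # <= 0
  db <- pmax(db, -floor_db)
  matrix(as.integer(round((db + floor_db) / floor_db * 255)),
         nrow(img), ncol(img))
}

#' Write a B-scan image file
#'
#' 8-bit PNG or 16-bit TIFF, linear or dB scale.
#'
#' @param b A `bscan`.
#' @param path Output path ending in `.png` or `.tif`/`.tiff`.
#' @param db If `TRUE`, write the [to_db_image()] dB mapping.
#' @param floor_db Dynamic-range floor for the dB mapping.
#' @return `path`, invisibly.
#' @export
write_bscan_image <- function(b, path, db = TRUE, floor_db = 40) {
  img <- if (db) to_db_image(b, floor_db) / 255 else {
    mx <- max(b$image)
    if (mx > 0) b$image / mx else b$image
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) abort("package 'png' is required")
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) abort("package 'tiff' is required")
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else {
    abort("path must end in .png, .tif or .tiff")
  }
  invisible(path)
}

#' Plot a B-scan
#'
#' @param object A `bscan`.
#' @param db If `TRUE`, display on a dB scale.
#' @param floor_db Dynamic-range floor for the dB display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bscan
#' @export
autoplot.bscan <- function(object, db = TRUE, floor_db = 40, ...) {
  df <- tidy(object)
  if (db && object$scale == "linear") {
    mx <- max(df$value)
    df$value <- if (mx > 0) {
      pmax(20 * log10(pmax(df$value, mx * 1e-6) / mx), -floor_db)
    } else -floor_db
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lateral, y = .data$depth_bin,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = if (db) "dB" else "a.u.") +
    ggplot2::labs(x = "lateral position (px)", y = "depth (bins)") +
    ggplot2::theme_minimal()
}

#' Plot a TCDE reconstruction profile
#'
#' Magnitude of the recovered full-range estimate against depth bin,
#' with the extracted peaks marked.
#'
#' @param object A `tcde_recon`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tcde_recon
#' @export
autoplot.tcde_recon <- function(object, ...) {
  df <- tibble(bin = seq_along(object$u_hat) - 1L,
               magnitude = Mod(object$u_hat))
  pk <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$magnitude)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$bin, yend = 0)) +
    ggplot2::geom_point(data = pk, color = "red", size = 1.5) +
    ggplot2::labs(x = "depth bin", y = "|S| (a.u.)") +
    ggplot2::theme_minimal()
}
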