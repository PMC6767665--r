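#' Read and write spectra as two-column text
#'
#' A-line spectra are exchanged as plain delimited text: comment header
#' lines (`# key: value`) carrying the spectrometer metadata, then two
#' columns `wavelength_nm` and `counts`.
#'
#' @param f Spectrum values (length = grid pixels).
#' @param grid The `spectral_grid` the spectrum is sampled on.
#' @param path Output path.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum`
#'   returns a list with `spectrum` and the reconstructed `grid`.
#' @export
write_spectrum <- function(f, grid, path) {
  stopifnot(inherits(grid, "spectral_grid"))
  if (length(f) != nrow(grid)) abort("spectrum length must match the grid")
  spec <- attr(grid, "spec")
  hdr <- c(
    sprintf("# center_wavelength_nm: %.17g", spec$center_wavelength),
    sprintf("# bandwidth_nm: %.17g", spec$bandwidth),
    sprintf("# spectral_resolution_nm: %.17g", spec$spectral_resolution),
    sprintf("# n_pixels: %d", spec$n_pixels),
    sprintf("# dialect: %s", grid_dialect(grid)),
    "wavelength_nm\tcounts"
  )
  body <- sprintf("%.17g\t%.17g", grid$wavelength_nm, as.numeric(f))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_val <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) abort(sprintf("missing header field '%s'", key))
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  spec <- spectrometer_spec(
    center_wavelength = as.numeric(get_val("center_wavelength_nm")),
    bandwidth = as.numeric(get_val("bandwidth_nm")),
    spectral_resolution = as.numeric(get_val("spectral_resolution_nm")),
    n_pixels = as.integer(get_val("n_pixels"))
  )
  grid <- build_grid(spec, dialect = get_val("dialect"))
  body <- lines[!grepl("^#", lines)][-1]          # drop the column header
  counts <- as.numeric(vapply(strsplit(body, "\t"), `[[`, "", 2))
  if (length(counts) != nrow(grid)) abort("pixel count does not match header")
  list(spectrum = counts, grid = grid)
}

#' Write an interferogram stack as delimited text
#'
#' Frames (lateral positions) by pixels, tab-separated, with a JSON
#' sidecar (`<path>.json`) echoing the spectrometer metadata.
#'
#' @param frames List of interferograms (or numeric vectors) of equal
#'   length.
#' @param grid The shared `spectral_grid`.
#' @param path Output path for the matrix; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, grid, path) {
  stopifnot(inherits(grid, "spectral_grid"))
  mat <- do.call(rbind, lapply(frames, as.numeric))
  if (ncol(mat) != nrow(grid)) abort("frame length must match the grid")
  utils::write.table(mat, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  spec <- attr(grid, "spec")
  jsonlite::write_json(
    list(center_wavelength_nm = spec$center_wavelength,
         bandwidth_nm = spec$bandwidth,
         spectral_resolution_nm = spec$spectral_resolution,
         n_pixels = spec$n_pixels, dialect = grid_dialect(grid),
         n_frames = nrow(mat)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mat <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(mat) <- NULL
  spec <- spectrometer_spec(meta$center_wavelength_nm, meta$bandwidth_nm,
                            meta$spectral_resolution_nm, meta$n_pixels)
  list(frames = lapply(seq_len(nrow(mat)), function(i) mat[i, ]),
       grid = build_grid(spec, dialect = meta$dialect))
}

#' Write a component table as delimited text
#'
#' One row per extracted peak: bin, depth in mm, magnitude, phase.
#'
#' @param recon A `tcde_recon`.
#' @param path Output path.
#' @param bin_size_m Axial bin size (metres) for the depth column.
#' @return `path`, invisibly.
#' @export
write_components <- function(recon, path, bin_size_m = NA_real_) {
  stopifnot(inherits(recon, "tcde_recon"))
  pk <- tidy(recon)
  n <- recon$mask$n
  signed_bin <- ifelse(pk$bin > n / 2, pk$bin - n, pk$bin)
  out <- data.frame(bin = pk$bin,
                    depth_mm = signed_bin * bin_size_m * 1e3,
                    magnitude = pk$magnitude, phase_rad = pk$phase_rad)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run provenance record
#'
#' A JSON echo of the configuration and seeds of a run, sufficient to
#' reproduce its deterministic stages bit for bit.
#'
#' @param path Output path.
#' @param ... Named configuration entries (lists are serialized as-is).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, ...) {
  entries <- list(...)
  entries$package_version <- as.character(utils::packageVersion("dcoct"))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
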