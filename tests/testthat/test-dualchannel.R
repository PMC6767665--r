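test_that("demux routes positive depths to channel 1 and wrapped negatives to channel 2", {
  n <- 1024L
  lay <- channel_layout(128L, n)
  u <- complex(length.out = n)
  u[5 + 1] <- 2                      # channel-1 bin 5
  u[n - 5 + 1] <- 1                  # channel-2 bin 5 (depth -5)
  dm <- demux(u, lay)
  c1 <- dm[dm$channel == 1, ]
  c2 <- dm[dm$channel == 2, ]
  expect_equal(c1$magnitude[c1$bin == 5], 2)
  expect_equal(sum(c1$magnitude > 0), 1)
  expect_equal(c2$magnitude[c2$bin == 5], 1)
  expect_equal(sum(c2$magnitude > 0), 1)

  # energy restricted to the two windows is conserved
  set.seed(1)
  u2 <- complex(real = rnorm(n), imaginary = rnorm(n))
  dm2 <- demux(u2, lay)
  win1 <- seq_len(lay$n_ch)
  win2 <- n - seq_len(lay$n_ch - 1L) + 1L
  expect_equal(sum(dm2$magnitude^2),
               sum(Mod(u2[win1])^2) + sum(Mod(u2[win2])^2))
})

test_that("mirrors separated by 2.8 mm of path appear at the expected bin distance", {
  n <- 960L
  grid <- oct_grid(n)
  dz <- depth_bin_size(grid)
  sep_bins <- round(2.8e-3 / dz)
  # place the two fringe components that many bins apart in optical path
  b1 <- 150L
  b2 <- sep_bins - b1                     # channel-2 depth -b2
  phi <- dispersion_phase(grid, dispersion_spec())
  f <- synthesize(mirror_phantom(b1, 1, 480, channel = 1L),
                  mirror_phantom(b2, 0.5, 480, channel = 2L),
                  phi, forward_config(d_bins = 240L), n)
  u <- Mod(de_transform(f, phi))
  pk <- order(u, decreasing = TRUE)[1:2] - 1L
  # signed optical-path distance between the two components, in bins
  d_signed <- pk[1] - (pk[2] - n)
  expect_equal(d_signed, sep_bins)
  expect_equal(round(sep_bins * dz * 1e3, 1), 2.8)
})

test_that("mode-1 stitching concatenates laterally with a flagged dead zone", {
  b1 <- bscan(matrix(1, 8, 5))
  b2 <- bscan(matrix(2, 8, 4))
  st0 <- stitch_mode1(b1, b2, dead_zone_px = 0)
  expect_equal(ncol(st0$image), 9)

  st <- stitch_mode1(b1, b2, dead_zone_px = 3)
  expect_equal(ncol(st$image), 12)
  expect_equal(st$stitched_gap_cols, 6:8)
  expect_true(all(st$image[, 6:8] == 0))
  # provenance columns map back to their source scans exactly
  expect_equal(st$source_cols, c(rep(1L, 5), rep(NA_integer_, 3), rep(2L, 4)))
  expect_true(all(st$image[, st$source_cols %in% 1] == 1))
  expect_true(all(st$image[, st$source_cols %in% 2] == 2))

  # empty second scan: the first is padded by the dead zone only
  st_empty <- stitch_mode1(b1, bscan(matrix(0, 8, 0)), dead_zone_px = 2)
  expect_equal(ncol(st_empty$image), 7)
  expect_equal(st_empty$image[, 1:5], b1$image)
})

test_that("mode-2 stitching doubles the depth extent and blends overlap by maximum", {
  up <- bscan(matrix(1, 10, 6))
  dp <- bscan(matrix(3, 10, 6))
  st <- stitch_mode2(up, dp, x_shift_px = 0, overlap_px = 0)
  expect_equal(nrow(st$image), 20)           # exactly twice one channel
  expect_equal(ncol(st$image), 6)

  # empty (all-zero) deep scan leaves the upper content unchanged
  st0 <- stitch_mode2(up, bscan(matrix(0, 10, 6)), 0, 0)
  expect_equal(st0$image[1:10, ], up$image)
  expect_true(all(st0$image[11:20, ] == 0))

  # overlap rows take the elementwise maximum
  sto <- stitch_mode2(up, dp, x_shift_px = 0, overlap_px = 4)
  expect_equal(nrow(sto$image), 16)
  expect_true(all(sto$image[7:10, ] == 3))

  # lateral shift crops to the common support
  sts <- stitch_mode2(up, dp, x_shift_px = 2, overlap_px = 0)
  expect_equal(ncol(sts$image), 4)

  expect_error(stitch_mode2(up, dp, x_shift_px = 6), "width")
})

test_that("snr_db closed forms and sentinel", {
  set.seed(7)
  floor_vals <- rnorm(40, 0, 1)
  ascan <- c(floor_vals, 100)
  expect_equal(snr_db(ascan, 40, 0:39), 20 * log10(100 / sd(floor_vals)))

  ascan2 <- c(floor_vals, sd(floor_vals))    # peak equal to the floor sd
  expect_equal(snr_db(ascan2, 40, 0:39), 0, tolerance = 1e-12)

  expect_equal(snr_db(c(rep(1, 20), 5), 20, 0:19), Inf)
  expect_error(snr_db(ascan, 40, 0:3), "at least 8")
  expect_error(snr_db(ascan, 10, 0:39), "exclude")
})

test_that("measured mirror SNR matches the analytic prediction within 1 dB", {
  n <- 1024L
  A <- 1
  sigma <- 0.5
  m <- 100L
  f0 <- synthesize_full(mirror_phantom(m, A, n), numeric(n))
  noise_win <- 300:700
  snrs <- vapply(1:100, function(s) {
    fn <- add_noise(f0, forward_config(noise_sd = sigma, seed = s))
    u <- Mod(de_transform(fn, numeric(n)))
    snr_db(u, m, noise_win)
  }, numeric(1))
  # depth-domain noise: complex Gaussian with E|.|^2 = 4 sigma^2 / N
  # (ifft scaled by 1/N then 1/R with R = 1/2); the sd of its magnitude is
  # sqrt(2 sigma^2/N) * sqrt(2 - pi/2)
  pred <- 20 * log10(A / (sqrt(2 * sigma^2 / n) * sqrt(2 - pi / 2)))
  expect_lt(abs(mean(snrs) - pred), 1)
})

test_that("dB images quantize to 0-255 with bounded round-trip error", {
  const <- bscan(matrix(5, 4, 4))
  img_const <- to_db_image(const, floor_db = 40)
  expect_true(all(img_const == img_const[1, 1]))

  zero <- bscan(matrix(0, 4, 4))
  expect_true(all(to_db_image(zero, 40) == 0))

  set.seed(3)
  vals <- matrix(10^runif(64, -1.5, 0), 8, 8)   # within the 40 dB window
  b <- bscan(vals)
  floor_db <- 40
  g <- to_db_image(b, floor_db)
  db_true <- pmax(20 * log10(vals / max(vals)), -floor_db)
  db_back <- g / 255 * floor_db - floor_db
  expect_lt(max(abs(db_back - db_true)), floor_db / 255 / 2 + 1e-9)
})

test_that("assembled per-channel B-scans pick each channel's content", {
  n <- 512L
  d <- 64L
  lay <- channel_layout(d, n)
  u <- complex(length.out = n)
  u[10 + 1] <- 1          # channel 1
  u[n - 30 + 1] <- 2      # channel 2, bin 30
  b1 <- assemble_bscan(list(u, u), lay, channel = 1L)
  b2 <- assemble_bscan(list(u, u), lay, channel = 2L)
  expect_equal(dim(b1$image), c(lay$n_ch, 2))
  expect_equal(which(b1$image[, 1] > 0) - 1L, 10L)
  expect_equal(which(b2$image[, 1] > 0) - 1L, 30L)
})
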