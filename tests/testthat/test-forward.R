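test_that("embedding places channel 1 at +depth and channel 2 at wrapped -depth", {
  u <- embed_full_range(mirror_phantom(5, 1, 32), NULL, d = 128, n = 1024)
  expect_equal(which(Mod(u) > 0) - 1L, 5L)

  u2 <- embed_full_range(NULL, mirror_phantom(5, 1, 32), d = 128, n = 1024)
  expect_equal(which(Mod(u2) > 0) - 1L, 1024L - 5L)

  # disjoint supports accumulate
  u3 <- embed_full_range(sparse_reflectors(c(3, 9), c(1, 2), 32),
                         sparse_reflectors(c(4, 11), c(1, 1), 32),
                         d = 128, n = 1024)
  expect_equal(sum(Mod(u3) > 0), 4)

  expect_error(embed_full_range(mirror_phantom(5, 1, 300), NULL, d = 128, n = 1024),
               "overlap")
})

test_that("synthesized spectra are real cosine fringes with the expected scaling", {
  n <- 256L
  expect_equal(as.numeric(synthesize_full(complex(length.out = n), numeric(n))),
               numeric(n))

  m <- 17L
  f <- synthesize_full(mirror_phantom(m, 1, n), numeric(n),
                       forward_config(r_reference = 0.5))
  i <- 0:(n - 1)
  expect_equal(as.numeric(f), cos(2 * pi * m * i / n), tolerance = 1e-12)
})

test_that("dispersion broadens the uncompensated transform but matched compensation sharpens it", {
  n <- 1024L
  phi <- oct_phase(n)
  f <- synthesize_full(oct_sparse_signal(n), phi)
  u_raw <- Mod(de_transform(f, numeric(n)))       # no compensation
  u_comp <- Mod(de_transform(f, phi))             # matched compensation
  # compensated peaks are sharp and amplitude-true
  expect_equal(u_comp[c(201, 251, 581)], c(3, 1, 0.1), tolerance = 0.01)
  # without compensation the structural peaks are broadened and reduced
  expect_lt(max(u_raw), 1.5)
  width_raw <- sum(u_raw > max(u_raw) / 2)
  expect_gt(width_raw, 10)
})

test_that("synthesis is linear and conserves DFT energy (Parseval bookkeeping)", {
  n <- 128L
  phi <- oct_phase(n)
  s1 <- sparse_reflectors(c(3, 7), c(1, 2), 32)
  s1b <- sparse_reflectors(10, 0.5, 32)
  s2 <- sparse_reflectors(5, 1.5, 32)
  cfg <- forward_config(d_bins = 32)
  f_sum <- synthesize(depth_profile(unclass(s1) + unclass(s1b)), s2, phi, cfg, n)
  f_parts <- as.numeric(synthesize(s1, s2, phi, cfg, n)) +
    as.numeric(synthesize(s1b, NULL, phi, cfg, n))
  expect_equal(as.numeric(f_sum), f_parts, tolerance = 1e-12)

  u <- embed_full_range(s1, s2, 32, n)
  expect_equal(sum(Mod(fft(u))^2), n * sum(Mod(u)^2), tolerance = 1e-12)
})

test_that("with channel 2 empty, full-sampling matched reconstruction stays in channel 1's window", {
  n <- 512L
  d <- 64L
  phi <- oct_phase(n)
  f <- synthesize(sparse_reflectors(c(20, 90), c(2, 1), 2 * d), NULL, phi,
                  forward_config(d_bins = d), n)
  mask <- make_mask(n, 1)
  rec <- tcde(apply_mask(f, mask), mask, phi)
  expect_true(all(tidy(rec)$bin < 2 * d))
})

test_that("detection noise is seed-reproducible with the configured sigma", {
  n <- 4096L
  f <- synthesize_full(mirror_phantom(40, 1, n), numeric(n))
  cfg0 <- forward_config(noise_sd = 0)
  expect_equal(as.numeric(add_noise(f, cfg0)), as.numeric(f))

  cfg <- forward_config(noise_sd = 1, seed = 11)
  n1 <- add_noise(f, cfg)
  n2 <- add_noise(f, cfg)
  expect_identical(as.numeric(n1), as.numeric(n2))
  expect_equal(sd(as.numeric(n1) - as.numeric(f)), 1, tolerance = 0.05)

  cfg_shot <- forward_config(shot_noise = TRUE, shot_offset = 1e4, seed = 3)
  sh <- add_noise(f, cfg_shot)
  expect_false(identical(as.numeric(sh), as.numeric(f)))
  # Poisson on offset-shifted counts: spread near sqrt(offset)
  expect_equal(sd(as.numeric(sh) - as.numeric(f)), sqrt(1e4), tolerance = 0.1 * sqrt(1e4))
})

test_that("B-scan simulation yields one interferogram per lateral position, in order", {
  n <- 128L
  n_ch <- 16L
  obj <- matrix(0 + 0i, nrow = n_ch, ncol = 6L)
  obj[4, 1:3] <- 1; obj[9, 4:6] <- 2
  sc <- two_channel_scene(1L, obj, n_ch = n_ch)
  frames <- simulate_bscan(sc, numeric(n), forward_config(d_bins = 16))
  expect_length(frames, 3L)
  # position 1 pairs column 1 (bin 3, ch 1) with column 4 (bin 8, ch 2)
  u1 <- de_transform(frames[[1]], numeric(n))
  pk <- order(Mod(u1), decreasing = TRUE)[1:4] - 1L
  expect_setequal(pk, c(3L, n - 3L, 8L, n - 8L))
})
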