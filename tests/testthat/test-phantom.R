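test_that("sparse reflector profiles carry exactly the requested nonzeros", {
  p <- sparse_reflectors(c(200, 250, 580), c(3, 1, 0.1), 1024)
  expect_s3_class(p, "depth_profile")
  expect_length(p, 1024)
  expect_equal(sum(Mod(p) > 0), 3)
  expect_equal(Mod(unclass(p))[c(201, 251, 581)], c(3, 1, 0.1))

  expect_equal(sum(Mod(sparse_reflectors(integer(), numeric(), 64)) > 0), 0)

  p1 <- sparse_reflectors(0, 1.0, 8)
  expect_equal(Mod(unclass(p1))[1], 1)
  expect_equal(sum(Mod(p1)), 1)

  expect_error(sparse_reflectors(c(1, 1), c(1, 2), 8), "distinct")
  expect_error(sparse_reflectors(8, 1, 8), "lie in")
})

test_that("mirror phantom is a single reflector; zero amplitude gives a zero profile", {
  p <- mirror_phantom(10, 1.0, 512)
  expect_equal(which(Mod(p) > 0) - 1L, 10L)
  expect_equal(sum(Mod(mirror_phantom(10, 0, 512))), 0)
})

test_that("layered phantom is seed-reproducible and attenuates with depth", {
  a <- layered_phantom(c(10, 40, 80), c(1, 1, 1), 0.3, 0.01, seed = 9, n = 128)
  b <- layered_phantom(c(10, 40, 80), c(1, 1, 1), 0.3, 0.01, seed = 9, n = 128)
  expect_identical(unclass(a), unclass(b))

  # no speckle, no attenuation: deterministic sparse profile
  d0 <- layered_phantom(c(10, 40), c(2, 3), 0, 0, seed = 1, n = 64)
  expect_equal(Mod(unclass(d0))[c(11, 41)], c(2, 3))

  # attenuation makes deeper equal-amplitude layers strictly weaker
  att <- layered_phantom(c(10, 40, 80), c(1, 1, 1), 0, 0.02, seed = 1, n = 128)
  mags <- Mod(unclass(att))[c(11, 41, 81)]
  expect_true(all(diff(mags) < 0))
})

test_that("speckle fraction is validated and speckled layers stay at layer bins", {
  expect_error(layered_phantom(1, 1, 1.5, 0, 1, n = 8), "0, 1")
  sp <- layered_phantom(c(5, 20), c(1, 1), 0.5, 0, seed = 3, n = 64)
  expect_equal(which(Mod(sp) > 0) - 1L, c(5L, 20L))
})

test_that("confocal window never increases magnitude at any bin", {
  p <- layered_phantom(c(5, 30, 60), c(1, 2, 3), 0.4, 0, seed = 2, n = 100)
  w <- confocal_window(p, focal_bin = 30, width_bins = 15)
  expect_true(all(Mod(w) <= Mod(p) + 1e-15))
  expect_lt(Mod(unclass(w))[61], Mod(unclass(p))[61])  # away from focus
})

test_that("mode-2 scenes split a doubled-depth object into upper/deep channels", {
  n_ch <- 32L
  obj <- matrix(0 + 0i, nrow = 2L * n_ch, ncol = 3L)
  obj[10, ] <- 1          # layer 1 in the upper half
  obj[n_ch + 20, ] <- 0.5 # layer 2 one full depth range deeper
  sc <- two_channel_scene(2L, obj, n_ch = n_ch)
  expect_equal(sc$n_lateral, 3L)
  s1 <- unclass(sc$pairs[[1]]$S1)
  s2 <- unclass(sc$pairs[[1]]$S2)
  expect_equal(which(Mod(s1) > 0) - 1L, 9L)
  expect_equal(which(Mod(s2) > 0) - 1L, 19L)

  # zero-thickness object: both channel profiles are empty
  sc0 <- two_channel_scene(2L, matrix(0 + 0i, 2L * n_ch, 2L), n_ch = n_ch)
  expect_equal(sum(Mod(unclass(sc0$pairs[[1]]$S1))), 0)
  expect_equal(sum(Mod(unclass(sc0$pairs[[1]]$S2))), 0)
})

test_that("mode-1 scenes give laterally adjacent same-depth channels", {
  n_ch <- 16L
  obj <- matrix(0 + 0i, nrow = n_ch, ncol = 2L)
  obj[5, 1] <- 1; obj[8, 2] <- 2
  sc <- two_channel_scene(1L, obj, n_ch = n_ch)
  expect_equal(sc$n_lateral, 1L)
  expect_equal(which(Mod(unclass(sc$pairs[[1]]$S1)) > 0) - 1L, 4L)
  expect_equal(which(Mod(unclass(sc$pairs[[1]]$S2)) > 0) - 1L, 7L)
  expect_error(two_channel_scene(3L, obj, n_ch), "mode")
})

test_that("mode-2 lateral offset shifts the deep channel", {
  n_ch <- 8L
  obj <- matrix(0 + 0i, nrow = 2L * n_ch, ncol = 4L)
  obj[n_ch + 3, 2] <- 1   # deep layer only at lateral position 2
  sc <- two_channel_scene(2L, obj, n_ch = n_ch, lateral_offset_px = 1L)
  hits <- vapply(sc$pairs, function(p) sum(Mod(unclass(p$S2))) > 0, logical(1))
  expect_equal(which(hits), 3L)   # channel 2 lags by one position
})
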