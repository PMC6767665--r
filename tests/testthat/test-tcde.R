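test_that("the depth transform equals the dense-matrix oracle at N = 64", {
  n <- 64L
  phi <- oct_phase(n)
  f <- synthesize_full(sparse_reflectors(c(5, 20), c(2, 1), n), phi)
  expect_equal(de_transform(f, phi), dense_de_oracle(as.numeric(f), phi),
               tolerance = 1e-10)
  expect_equal(reconstruct_full(f, phi), de_transform(f, phi))
})

test_that("without dispersion a real fringe gives two equal conjugate peaks", {
  n <- 256L
  m <- 30L
  f <- synthesize_full(mirror_phantom(m, 1, n), numeric(n))
  u <- Mod(de_transform(f, numeric(n)))
  expect_equal(u[m + 1], u[n - m + 1])
  expect_equal(u[m + 1], 1, tolerance = 1e-12)
})

test_that("matched dispersion suppresses the conjugate relative to the true peak", {
  n <- 1024L
  phi <- oct_phase(n)
  m <- 200L
  f <- synthesize_full(mirror_phantom(m, 1, n), phi)
  u <- Mod(de_transform(f, phi))
  expect_gt(u[m + 1], u[n - m + 1])
  # the whole broadened conjugate neighborhood stays well below the peak
  conj_win <- ((n - m - 40):(n - m + 40)) + 1
  expect_gt(u[m + 1], 3 * max(u[conj_win]))
})

test_that("component extraction keeps peaks with neighbors and resolves conjugate pairs", {
  # all below threshold: empty
  u <- complex(modulus = rep(0.1, 64), argument = 0)
  expect_equal(nrow(extract_components(u, threshold = 1)), 0)

  # one peak, w = 1: the peak and its previous/next bins are kept
  n <- 1024L
  u <- complex(length.out = n)
  u[201] <- 5
  cm <- extract_components(u, threshold = 1, w = 1)
  expect_equal(sort(cm$bin), c(199L, 200L, 201L))
  expect_equal(unique(cm$peak_bin), 200L)

  # of a conjugate pair only the larger survives
  u2 <- complex(length.out = n)
  u2[201] <- 2; u2[n - 200 + 1] <- 1
  cm2 <- extract_components(u2, threshold = 0.5, w = 0)
  expect_equal(cm2$bin, 200L)

  # exact tie: the lower bin wins
  u3 <- complex(length.out = n)
  u3[201] <- 2; u3[n - 200 + 1] <- 2
  cm3 <- extract_components(u3, threshold = 0.5, w = 0)
  expect_equal(cm3$bin, 200L)
})

test_that("predicted spectra re-synthesize components through the forward operator", {
  n <- 512L
  phi <- oct_phase(n)
  mk_full <- make_mask(n, 1)
  expect_equal(predict_spectrum(tibble::tibble(bin = integer(),
                                               amplitude = complex()),
                                phi, mk_full), numeric(n))

  comp <- tibble::tibble(bin = 37L, amplitude = 1.5 + 0i)
  pred <- predict_spectrum(comp, phi, mk_full)
  direct <- synthesize_full(sparse_reflectors(37, 1.5, n), phi)
  expect_equal(pred, as.numeric(direct), tolerance = 1e-12)

  # linear in the component list
  c1 <- tibble::tibble(bin = 10L, amplitude = 1 + 0i)
  c2 <- tibble::tibble(bin = 60L, amplitude = 0 + 2i)
  mk <- make_mask(n, 0.4, seed = 2)
  expect_equal(predict_spectrum(dplyr::bind_rows(c1, c2), phi, mk),
               predict_spectrum(c1, phi, mk) + predict_spectrum(c2, phi, mk),
               tolerance = 1e-12)
})

test_that("TCDE at full sampling recovers the sparse support without conjugates", {
  run <- run_sparse_demo(rate = 1, seed = 1)
  pk <- tidy(run$recon)
  expect_true(all(c(200, 250, 580) %in% pk$bin))
  expect_false(any((1024 - c(200, 250, 580)) %in% pk$bin))
  expect_equal(recovered_amplitude(run$recon, 200), 3, tolerance = 0.01)
  expect_equal(recovered_amplitude(run$recon, 250), 1, tolerance = 0.01)
  expect_equal(recovered_amplitude(run$recon, 580), 0.1, tolerance = 0.01)
  # strong components in iteration 1, the weak one in iteration 2
  expect_equal(sort(pk$bin[pk$iteration == 1]), c(200L, 250L))
  expect_equal(pk$bin[pk$iteration == 2], 580L)
})

test_that("TCDE at rate 1 matches thresholded full reconstruction", {
  n <- 1024L
  phi <- oct_phase(n)
  f <- synthesize_full(oct_sparse_signal(n), phi)
  mask <- make_mask(n, 1)
  cfg <- recon_config()
  rec <- tcde(apply_mask(f, mask), mask, phi, cfg)
  u_full <- reconstruct_full(f, phi)
  direct <- extract_components(u_full, cfg$alpha * max(Mod(u_full)),
                               w = cfg$w,
                               conjugate_window = cfg$conjugate_window)
  it1 <- tidy(rec)$bin[tidy(rec)$iteration == 1]
  expect_setequal(it1, unique(direct$peak_bin))
})

test_that("an all-zero spectrum yields a flagged empty reconstruction, not an error", {
  n <- 256L
  mk <- make_mask(n, 0.5, seed = 1)
  rec <- tcde(numeric(mk$m), mk, numeric(n))
  expect_true(rec$empty)
  expect_equal(nrow(rec$components), 0)
  expect_equal(Mod(rec$u_hat), numeric(n))
  expect_equal(rec$residual_energy, 0)
})

test_that("residual energy never increases across iterations", {
  n <- 1024L
  phi <- oct_phase(n)
  f <- synthesize_full(oct_sparse_signal(n), phi)
  for (s in 1:8) {
    mk <- make_mask(n, 0.3, seed = s)
    rec <- tcde(apply_mask(f, mk), mk, phi,
                recon_config(n_iterations = 4, max_iterations = 4))
    expect_true(all(diff(rec$residual_energy) <= 1e-9))
  }
})

test_that("iteration-1 extraction matches a brute-force single-component fit (N = 64, K = 1)", {
  n <- 64L
  phi <- oct_phase(n)
  true_bin <- 20L
  f <- synthesize_full(mirror_phantom(true_bin, 1, n), phi)
  for (s in 1:5) {
    mk <- make_mask(n, 0.4, seed = s)
    fu <- apply_mask(f, mk)
    # oracle: least-squares fit of one complex component at every bin
    rss <- vapply(0:(n - 1), function(b) {
      i0 <- mk$indices - 1
      th <- phi[i0 + 1] - 2 * pi * i0 * b / n
      A <- cbind(cos(th), -sin(th))
      fit <- lm.fit(A, fu)
      sum(fit$residuals^2)
    }, numeric(1))
    best <- which.min(rss) - 1L
    rec <- tcde(fu, mk, phi, recon_config(n_iterations = 1))
    expect_equal(tidy(rec)$bin[1], best)
    expect_equal(best, true_bin)
  }
})

test_that("support recovery improves monotonically with sampling rate", {
  rates <- c(0.1, 0.2, 0.5, 1.0)
  seeds <- 1:50
  mean_f1 <- vapply(rates, function(r) {
    mean(vapply(seeds, function(s) {
      run <- run_sparse_demo(rate = r, seed = s)
      recovery_f1(run$recon, c(200, 250, 580))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_f1) >= -1e-9))
  expect_equal(mean_f1[4], 1)
})

test_that("the weak mirror's recovery probability collapses between 20% and 10% sampling", {
  sw <- run_rate_sweep(rates = c(0.2, 0.1), seeds = 1:25)
  p <- tapply(sw$small_recovered, sw$rate, mean)
  expect_gt(p[["0.2"]], 0.7)
  expect_lt(p[["0.1"]], p[["0.2"]] - 0.25)
})

test_that("recon_config validates its parameters", {
  expect_error(recon_config(n_iterations = 0), "n_iterations")
  expect_error(recon_config(alpha = 1.5), "alpha")
  expect_error(recon_config(beta = -1), "beta")
  expect_error(recon_config(w = -1), "w")
})
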