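test_that("svd_filter removes low-order clutter and preserves energy accounting", {
  # rank-3 pure clutter, cutoff 3: residual energy < 1% of input
  cfgc <- phantom_config(clutter_rank = 3, noise_sigma = 0, seed = 2)
  stc <- render_iq(empty_tracks(), cfgc, grid = grid_native(48L),
                   frame_rate = 1000, n_frames = 80)
  fl <- svd_filter(stc, rank_mode = "fixed", rank = 3)
  expect_lt(iq_energy(fl$stack) / iq_energy(stc), 0.01)

  # cutoff 0: identity
  fl0 <- svd_filter(stc, rank_mode = "fixed", rank = 0)
  expect_identical(fl0$stack$data, stc$data)

  # energy partition: removed + kept = input
  removed <- iq_energy(stc) - iq_energy(fl$stack)
  expect_equal(removed + iq_energy(fl$stack), iq_energy(stc),
               tolerance = 1e-9)
  expect_equal(removed, sum(fl$decomposition$singular_values[1:3]^2),
               tolerance = 1e-6)

  # singular values are non-negative and non-increasing
  sv <- fl$decomposition$singular_values
  expect_true(all(sv >= 0) && all(diff(sv) <= 1e-8))

  expect_error(svd_filter(stc, rank_mode = "fixed", rank = 80), "n_frames")
})

test_that("projection idempotence: sequential cutoffs equal the single larger cutoff", {
  set.seed(11)
  arr <- array(complex(real = rnorm(16 * 16 * 24), imaginary = rnorm(16 * 16 * 24)),
               dim = c(16, 16, 24))
  st <- iq_stack(arr, 19.712, 1000)
  a <- svd_filter(st, rank_mode = "fixed", rank = 2)
  b <- svd_filter(a$stack, rank_mode = "fixed", rank = 3)
  direct <- svd_filter(st, rank_mode = "fixed", rank = 5)
  expect_equal(b$stack$data, direct$stack$data, tolerance = 1e-8)
  # oracle: brute-force svd reconstruction on the Casorati matrix
  X <- matrix(st$data, ncol = 24)
  s <- svd(X)
  Xf <- s$u[, 6:24] %*% diag(s$d[6:24]) %*% Conj(t(s$v[, 6:24]))
  expect_equal(direct$stack$data, array(Xf, dim = dim(st$data)),
               tolerance = 1e-8)
})

test_that("adaptive_rank_select finds the clutter knee and flags degenerate spectra", {
  # constructed spectrum: three clutter values then a noise plateau
  sv <- c(1e4, 1e3, 1e2, stats::runif(200, 0.9, 1.1))
  sv <- sort(sv, decreasing = TRUE)
  k <- adaptive_rank_select(sv)
  expect_true(abs(k - 3) <= 1)

  # log-linear spectrum: no knee
  expect_error(adaptive_rank_select(10^seq(4, 0, length.out = 50)),
               "degenerate")
  expect_error(adaptive_rank_select(rep(5, 20)), "degenerate")
  expect_error(adaptive_rank_select(c(10, 1)), "at least 8")

  # phantom with clutter rank 5 (+ bubbles + noise): cutoff in [4, 7]
  # (0.4 s record: slow envelopes need a few cycles to be separable)
  g <- tiny_geom()
  tr <- simulate_tracks(g, 0.4, 1000, bubble_rate = 2, seed = 3)
  cfg <- phantom_config(clutter_rank = 5, clutter_amp = 30,
                        noise_sigma = 0.05, seed = 5)
  st <- render_iq(tr, cfg, grid = grid_native(), n_frames = 400)
  fl <- svd_filter(st, rank_mode = "adaptive")
  expect_gte(fl$decomposition$cutoff, 4)
  expect_lte(fl$decomposition$cutoff, 7)
})

test_that("noise_equalize flattens the depth profile", {
  # uniform noise: estimated profile ~ constant, output ~ input
  cfgu <- phantom_config(clutter_rank = 0, noise_sigma = 0.1,
                         noise_depth_slope = 0, seed = 6)
  stu <- render_iq(empty_tracks(), cfgu, grid = grid_native(64L),
                   frame_rate = 1000, n_frames = 200)
  equ <- noise_equalize(stu)
  prof <- attr(equ, "noise_profile")
  expect_lt(diff(range(prof)), 0.1)
  expect_equal(Mod(equ$data), Mod(stu$data) / as.numeric(prof),
               tolerance = 1e-12)

  # g(z) = 1 + z/z_max: post-equalization RMS-vs-depth slope ~ 0
  cfgn <- phantom_config(clutter_rank = 0, noise_sigma = 0.1,
                         noise_depth_slope = 1, seed = 7)
  stn <- render_iq(empty_tracks(), cfgn, grid = grid_native(64L),
                   frame_rate = 1000, n_frames = 300)
  eq <- noise_equalize(stn)
  rms <- sqrt(rowMeans(matrix(Mod(eq$data)^2, nrow = 64)))
  z <- seq_len(64) / 64   # depth as a fraction of z_max
  slope <- coef(lm(rms / mean(rms) ~ z))[2]
  expect_lt(abs(slope), 0.05)

  # explicit profile: exact, invertible division
  p <- noise_profile(seq(1, 2, length.out = 64))
  eqp <- noise_equalize(stn, p)
  back <- eqp$data * as.numeric(p)
  expect_equal(back, stn$data, tolerance = 1e-12)

  expect_error(noise_profile(c(1, -1, 1)), "positive")
  expect_error(noise_profile(c(1, 2, 1)), "smooth")
  expect_error(noise_equalize(stn, rep(1, 10)), "length")
})

test_that("power_doppler is the temporal mean of |IQ|^2", {
  set.seed(8)
  fr <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  st1 <- iq_stack(array(fr, dim = c(8, 8, 1)), 10, 1000)
  expect_equal(power_doppler(st1), Mod(fr)^2)

  # two frames of equal magnitude -> same image as either
  st2 <- iq_stack(array(c(fr, fr * exp(1i * 0.7)), dim = c(8, 8, 2)), 10, 1000)
  expect_equal(power_doppler(st2), Mod(fr)^2, tolerance = 1e-12)

  # phantom: bright set overlaps the vessel footprint (Dice > 0.5)
  g <- tiny_geom()
  tr <- simulate_tracks(g, 0.3, 1000, bubble_rate = 1, seed = 4)
  cfg <- phantom_config(clutter_rank = 0, noise_sigma = 0.03, seed = 4)
  st <- render_iq(tr, cfg, grid = grid_native(), n_frames = 300)
  pd <- power_doppler(st)
  bright <- pd >= quantile(pd, 0.95)
  # vessel footprint: pixels within R + half PSF width of the centerline
  zc <- 2523.1 / 2
  zg <- (0:127) * 19.712
  xg <- (0:127) * 19.712
  fp <- outer(abs(zg - zc) <= 25 + 40, xg >= 252 & xg <= 2271, "&")
  dice <- 2 * sum(bright & fp) / (sum(bright) + sum(fp))
  expect_gt(dice, 0.5)
})

test_that("estimate_heart_rate recovers cardiac modulation from pulsatility", {
  cfg <- phantom_config(clutter_rank = 2, clutter_amp = 10, cardiac_mod = 0.15,
                        cardiac_freq_hz = 7, noise_sigma = 0.02, seed = 2)
  st <- render_iq(empty_tracks(), cfg, grid = list(nz = 32, nx = 32, spacing_um = 19.712),
                  frame_rate = 1000, n_frames = 8000)
  expect_lt(abs(estimate_heart_rate(st) - 420), 5)

  # modulation depth 0: no peak above the noise floor
  cfg0 <- phantom_config(clutter_rank = 2, clutter_amp = 10, cardiac_mod = 0,
                         noise_sigma = 0.02, seed = 2)
  st0 <- render_iq(empty_tracks(), cfg0, grid = list(nz = 16, nx = 16, spacing_um = 19.712),
                   frame_rate = 1000, n_frames = 4000)
  expect_error(estimate_heart_rate(st0), "no pulsatility")

  # 6.9 Hz: periodogram-resolution example (16 s record, 16 x 16 grid)
  cfg69 <- phantom_config(clutter_rank = 2, clutter_amp = 10, cardiac_mod = 0.15,
                          cardiac_freq_hz = 6.9, noise_sigma = 0.02, seed = 3)
  st69 <- render_iq(empty_tracks(), cfg69, grid = list(nz = 16, nx = 16, spacing_um = 19.712),
                    frame_rate = 1000, n_frames = 16000)
  expect_lt(abs(estimate_heart_rate(st69) - 414), 3)
})
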