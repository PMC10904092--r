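test_that("vessel tree presets satisfy their geometric contracts", {
  # straight: collinear centerline
  g <- make_vessel_tree("straight")
  cl <- g$vessels[[1]]$centerline
  d <- cl[nrow(cl), ] - cl[1, ]
  cross <- (cl[, 1] - cl[1, 1]) * d[2] - (cl[, 2] - cl[1, 2]) * d[1]
  expect_lt(max(abs(cross)), 1e-6)

  # semicircle: finite-difference curvature ~ 1/R everywhere
  g2 <- make_vessel_tree("semicircle", r_curve_um = 200, n_points = 400)
  cl2 <- g2$vessels[[1]]$centerline
  v1 <- diff(cl2)
  curv <- vapply(seq_len(nrow(v1) - 1), function(i) {
    a <- v1[i, ]; b <- v1[i + 1, ]
    2 * abs(a[1] * b[2] - a[2] * b[1]) /
      (sqrt(sum(a^2)) * sqrt(sum(b^2)) * sqrt(sum((a + b)^2)))
  }, numeric(1))
  expect_true(all(abs(curv - 1 / 200) < 0.02 / 200))

  # bifurcation: three centerlines sharing one junction point
  g3 <- make_vessel_tree("bifurcation")
  ends <- lapply(g3$vessels, function(v) v$centerline)
  junction <- ends[[1]][nrow(ends[[1]]), ]
  expect_length(g3$vessels, 3)
  expect_equal(ends[[2]][1, ], junction, tolerance = 1e-9)
  expect_equal(ends[[3]][1, ], junction, tolerance = 1e-9)

  # cortical_column: one descending + one ascending vessel
  g4 <- make_vessel_tree("cortical_column")
  dz <- vapply(g4$vessels, function(v) {
    cl <- v$centerline; cl[nrow(cl), 1] - cl[1, 1]
  }, numeric(1))
  expect_true(any(dz > 0) && any(dz < 0))

  expect_error(make_vessel_tree("spiral"))
  expect_error(make_vessel_tree("straight", radius_um = -1), "positive")
  expect_error(make_vessel_tree("semicircle", r_curve_um = 5000), "field of view")
})

test_that("simulated tracks follow the Poiseuille profile", {
  g <- tiny_geom()
  tr <- simulate_tracks(g, duration_s = 0.5, frame_rate = 1000,
                        bubble_rate = 20, seed = 7)
  # uniform-over-area seeding: mean speed -> v_peak / 2 (analytic dA integral)
  sp <- tr$speed_mms[!duplicated(tr$bubble_id)]
  expect_gt(length(sp), 5000)
  expect_lt(abs(mean(sp) - 4) / 4, 0.02)
  expect_true(all(sp > 0 & sp <= 8))

  # per-bubble speed constant; frames strictly increasing; step length
  # equals speed / frame_rate
  one <- tr[tr$bubble_id == tr$bubble_id[1], ]
  expect_true(all(diff(one$frame) == 1))
  steps <- sqrt(diff(one$z_um)^2 + diff(one$x_um)^2)
  expect_equal(steps, rep(one$speed_mms[1], length(steps)), tolerance = 1e-6)

  # conservation: every entered bubble yields one ground-truth track
  expect_identical(length(unique(tr$bubble_id)), attr(tr, "n_entered"))

  # determinism
  tr2 <- simulate_tracks(g, duration_s = 0.5, frame_rate = 1000,
                         bubble_rate = 20, seed = 7)
  expect_identical(tr, tr2)

  expect_error(simulate_tracks(g, duration_s = -1, bubble_rate = 1), "positive")
  expect_error(simulate_tracks(g, duration_s = 1, bubble_rate = 0), "positive")
})

test_that("rendered IQ stacks superpose bubbles, clutter and noise linearly", {
  sp <- 19.712
  # one static bubble, no clutter/noise: every frame equals the echo kernel
  tr <- structure(data.frame(bubble_id = 1L, vessel = 1L, frame = 1:5,
                             z_um = 500, x_um = 700, speed_mms = 0),
                  frame_rate = 1000, class = c("ground_truth_tracks", "data.frame"))
  cfg0 <- phantom_config(clutter_rank = 0, noise_sigma = 0, cardiac_mod = 0,
                         seed = 1)
  st <- render_iq(tr, cfg0, grid = grid_native(64L), n_frames = 5)
  m1 <- Mod(st$data[, , 1])
  for (f in 2:5) expect_equal(Mod(st$data[, , f]), m1, tolerance = 1e-12)
  ref <- gauss_frame(500, 700, n = 64L)
  # rendered echoes are truncated at 3 sigma (tail value e^-4.5 ~ 0.011)
  expect_lt(max(abs(m1 / max(m1) - ref / max(ref))), 0.012)

  # clutter only: Casorati numerical rank equals the configured rank
  cfgc <- phantom_config(clutter_rank = 3, noise_sigma = 0, seed = 2)
  stc <- render_iq(empty_tracks(), cfgc, grid = grid_native(48L),
                   frame_rate = 1000, n_frames = 60)
  sv <- svd(matrix(stc$data, ncol = 60))$d
  expect_gt(sv[3] / sv[1], 1e-8)
  expect_lt(sv[4] / sv[1], 1e-10)

  # noise only: per-depth RMS proportional to the stated gain within 5%
  cfgn <- phantom_config(clutter_rank = 0, noise_sigma = 0.1,
                         noise_depth_slope = 1, seed = 3)
  stn <- render_iq(empty_tracks(), cfgn, grid = grid_native(64L),
                   frame_rate = 1000, n_frames = 300)
  rms <- sqrt(rowMeans(matrix(Mod(stn$data)^2, nrow = 64)))
  g <- 1 + (seq_len(64) - 1) / 63
  ratio <- rms / (g * rms[1] / g[1])
  expect_true(all(abs(ratio - 1) < 0.05))

  # linearity: union render = A + B - shared clutter/noise background
  g0 <- tiny_geom()
  trab <- simulate_tracks(g0, 0.05, 1000, bubble_rate = 2, seed = 9)
  ids <- unique(trab$bubble_id)
  a_ids <- ids[seq_along(ids) %% 2 == 1]
  cfg <- phantom_config(clutter_rank = 2, noise_sigma = 0.05, seed = 4)
  grid <- grid_native(64L)
  trab$z_um <- trab$z_um / 2; trab$x_um <- trab$x_um / 2  # fit 64-px grid
  stAB <- render_iq(trab, cfg, grid, n_frames = 50)
  stA <- render_iq(trab[trab$bubble_id %in% a_ids, ], cfg, grid, n_frames = 50,
                   frame_rate = 1000)
  stB <- render_iq(trab[!trab$bubble_id %in% a_ids, ], cfg, grid, n_frames = 50,
                   frame_rate = 1000)
  bg <- render_iq(empty_tracks(), cfg, grid, frame_rate = 1000, n_frames = 50)
  expect_equal(stAB$data, stA$data + stB$data - bg$data, tolerance = 1e-9)

  # determinism: identical config => identical stack
  st2 <- render_iq(trab, cfg, grid, n_frames = 50)
  expect_identical(stAB$data, st2$data)

  expect_error(render_iq(trab, cfg, grid = list(nz = 16, nx = 16, spacing_um = 19.712),
                         n_frames = 50), "mismatch")
})

test_that("histology phantom records ground truth and exercises the threshold", {
  # zero plaque density -> zero amyloid truth
  h0 <- render_histology(plaque_density = 0, size_px = c(128, 128), seed = 1)
  expect_equal(h0$truth$fraction_pct[h0$truth$channel == "abeta"], 0)

  # FITC truth equals the constructed ring fraction
  expect_equal(h0$truth$fraction_pct[h0$truth$channel == "fitc"],
               100 * sum(h0$truth_fitc) / prod(dim(h0$fitc)))

  # illumination field: global threshold misestimates area, adaptive does not
  h <- render_histology(plaque_density = 40, size_px = c(256, 256),
                        illumination = TRUE, seed = 5)
  truth_frac <- h$truth$fraction_pct[h$truth$channel == "abeta"]
  ad <- adaptive_threshold(h$abeta, window_px = 61)
  ad_err <- abs(positive_area_fraction(ad) - truth_frac)
  # global threshold at the same nominal level (factor x global median)
  gl <- h$abeta > 1.5 * median(h$abeta)
  gl_err <- abs(positive_area_fraction(gl) - truth_frac)
  expect_lt(ad_err, gl_err)

  expect_error(render_histology(plaque_density = -1), "non-negative")
})
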