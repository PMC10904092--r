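test_that("hobby_curve interpolates control vertices smoothly", {
  # square: curve symmetric under rotating the input vertices
  sq <- rbind(c(0, 0), c(0, 100), c(100, 100), c(100, 0))
  c1 <- hobby_curve(sq)
  c2 <- hobby_curve(sq[c(2, 3, 4, 1), ])
  # rotating input by one vertex shifts the curve by one segment
  nseg <- nrow(c1) / 4
  expect_equal(c1[(nseg + 1):(2 * nseg), ], unname(c2[1:nseg, ]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # passes through every control vertex
  for (i in 1:4) expect_equal(unname(c1[(i - 1) * nseg + 1, ]), unname(sq[i, ]),
                              tolerance = 1e-9)

  # vertices equally spaced on a circle: radial deviation < 1% of radius
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  circ <- cbind(200 + 150 * cos(th), 300 + 150 * sin(th))
  cc <- hobby_curve(circ)
  r <- sqrt((cc[, 1] - 200)^2 + (cc[, 2] - 300)^2)
  expect_lt(max(abs(r - 150)), 0.01 * 150)

  # collinear triple: closed curve without self-intersection
  col3 <- rbind(c(0, 0), c(0, 50), c(0, 100), c(60, 50))
  cv <- hobby_curve(col3)
  segs <- cbind(cv, rbind(cv[-1, ], cv[1, ]))
  n <- nrow(segs)
  crosses <- 0
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      hit <- ulmr:::.seg_intersect(segs[i, 1:2], segs[i, 3:4],
                                   segs[j, 1:2], segs[j, 3:4])
      if (!is.null(hit) && hit > 1e-9 && hit < 1 - 1e-9) crosses <- crosses + 1
    }
  }
  expect_identical(crosses, 0)

  expect_error(hobby_curve(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(hobby_curve(rbind(c(0, 0), c(0, 0), c(1, 1))), "duplicate")
  expect_error(hobby_curve(sq, closed = FALSE), "closed")
})

test_that("rasterize_roi fills closed curves by the even-odd rule", {
  grid <- list(nz = 50, nx = 50, spacing_um = 1)
  # axis-aligned square covering pixel centres 10..20
  sqc <- rbind(c(9.5, 9.5), c(9.5, 20.5), c(20.5, 20.5), c(20.5, 9.5))
  m <- rasterize_roi(sqc, grid)
  expect_identical(sum(m), 121L)
  expect_true(all(m[11:21, 11:21]))
  # translation equivariance
  m2 <- rasterize_roi(sqc + 5, grid)
  expect_identical(m2[16:26, 16:26], m[11:21, 11:21])
  # circle: area within 2% of pi R^2
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- cbind(25 + 15 * cos(th), 25 + 15 * sin(th))
  mc <- rasterize_roi(circ, grid)
  expect_lt(abs(sum(mc) - pi * 15^2) / (pi * 15^2), 0.02)
  expect_error(rasterize_roi(circ[1:2, ], grid), "curve")
})

test_that("vascularity and median velocity summarize the ROI rasters", {
  grid <- list(nz = 40, nx = 40, spacing_um = 4.928)
  roi <- roi_polygon(rbind(c(10, 10), c(10, 180), c(180, 180), c(180, 10)),
                     grid, label = "sq")
  empty_map <- accumulate(list(), grid)
  expect_equal(vascularity(empty_map, roi), 0)
  expect_error(median_velocity(empty_map, roi), "no perfused")

  # density everywhere in the ROI -> 100%
  full <- empty_map
  full$density[] <- 1L
  full$velocity[] <- 5
  expect_equal(vascularity(full, roi), 100)
  expect_equal(median_velocity(full, roi), 5)

  # two equal-area halves at 4 and 6 mm/s -> median 5
  half <- full
  idx <- which(roi$mask)
  if (length(idx) %% 2 == 1) idx <- idx[-1]
  half$velocity[idx[seq_len(length(idx) / 2)]] <- 4
  half$velocity[idx[(length(idx) / 2 + 1):length(idx)]] <- 6
  expect_equal(median_velocity(half, roi), 5)

  expect_error(vascularity(full, matrix(FALSE, 40, 40)), "empty ROI")
})

test_that("soam measures tortuosity in rad/mm with the stated invariances", {
  # collinear track -> 0
  expect_equal(soam(line_track(20)), 0, tolerance = 1e-12)
  # two 1 mm steps at a right angle -> (pi/2) / 2
  expect_equal(soam(mk_track(c(0, 1000, 1000), c(0, 0, 1000))), pi / 4)
  # densely sampled semicircle of radius R -> 1/R per mm
  th <- seq(0, pi, length.out = 150)
  semi <- cbind(200 * sin(th), 200 * cos(th))
  expect_lt(abs(soam(semi) - 5) / 5, 0.02)

  # rigid-motion invariance and 1/s scaling
  set.seed(9)
  pts <- cbind(cumsum(runif(12, 2, 6)), cumsum(rnorm(12, 0, 3)))
  a <- 0.7
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  expect_equal(soam(pts %*% R + 50), soam(pts), tolerance = 1e-9)
  expect_equal(soam(pts * 3), soam(pts) / 3, tolerance = 1e-9)

  expect_error(soam(mk_track(c(0, 1), c(0, 0))), "at least 3")
  expect_warning(soam(rbind(c(0, 0), c(0, 0), c(1, 0), c(2, 1))), "zero-length")
})

test_that("roi_soam averages over majority-inside tracks", {
  grid <- list(nz = 60, nx = 60, spacing_um = 4.928)
  roi <- roi_polygon(rbind(c(5, 5), c(5, 140), c(140, 140), c(140, 5)),
                     grid, label = "sq")
  straight <- line_track(n = 12, z = 50, x0 = 10, step = 4)
  bent <- mk_track(c(seq(20, 60, by = 10), seq(60, 20, by = -10)),
                   c(seq(20, 60, by = 10), seq(70, 110, by = 10)))
  expect_equal(roi_soam(list(straight), roi), 0, tolerance = 1e-12)
  expect_equal(roi_soam(list(bent), roi), soam(bent))
  expect_equal(roi_soam(list(straight, bent), roi),
               mean(c(0, soam(bent))), tolerance = 1e-12)
  # a track outside the ROI is ignored
  far <- line_track(n = 12, z = 280, x0 = 200, step = 4)
  expect_equal(roi_soam(list(straight, far), roi), 0, tolerance = 1e-12)
})

test_that("split_arteriole_venule classifies by the surface normal", {
  grid <- list(nz = 120, nx = 120, spacing_um = 4.928)
  roi <- roi_polygon(rbind(c(5, 5), c(5, 580), c(580, 580), c(580, 5)),
                     grid, label = "ctx", surface_normal = c(1, 0))
  down <- mk_track(seq(50, 500, by = 50), rep(100, 10))   # deeper over time
  up <- mk_track(rev(seq(50, 500, by = 50)), rep(300, 10))
  spl <- split_arteriole_venule(list(down, up), roi)
  expect_length(spl$arteriole, 1)
  expect_length(spl$venule, 1)
  expect_identical(spl$index, c("arteriole", "venule"))
  # reversing a track flips its label
  rev_down <- mk_track(rev(seq(50, 500, by = 50)), rep(100, 10))
  spl2 <- split_arteriole_venule(list(rev_down), roi)
  expect_identical(spl2$index, "venule")
  # partition property: arteriole + venule + excluded covers all ROI tracks
  expect_identical(length(spl$arteriole) + length(spl$venule) + spl$excluded,
                   sum(!is.na(spl$index)))
})

test_that("vessel_profile and fit_parabola recover Poiseuille parameters", {
  # single crossing track -> single-bin profile
  one <- mk_track(c(90, 110), c(100, 100))
  seg <- rbind(c(100, 80), c(100, 120))
  pr1 <- vessel_profile(list(one), seg)
  expect_identical(nrow(pr1), 1L)
  expect_identical(sum(pr1$n), 1L)

  # segment parallel to flow: no crossings
  par <- mk_track(rep(90, 5), seq(80, 120, by = 10))
  expect_error(vessel_profile(list(par), rbind(c(100, 80), c(100, 120))),
               "no track crosses")

  # exact parabola samples: parameters recovered to 1e-6
  r <- seq(2.5, 97.5, by = 5)
  v <- 8 * (1 - ((r - 50) / 30)^2)
  prof <- structure(data.frame(offset_um = r, v_max = v, v_mean = v,
                               n = rep(5L, length(r))),
                    class = c("vessel_profile", "data.frame"))
  fit <- fit_parabola(prof)
  expect_equal(fit$v_peak_mms, 8, tolerance = 1e-6)
  expect_equal(fit$center_um, 50, tolerance = 1e-6)
  expect_equal(fit$radius_um, 30, tolerance = 1e-6)

  # flat profile: flagged degenerate
  flat <- prof
  flat$v_max <- 5
  expect_error(fit_parabola(flat), "concave|unbounded")

  # Poiseuille phantom: per-bin max increases toward the tube axis
  g <- tiny_geom()
  tr <- simulate_tracks(g, 1.5, 1000, bubble_rate = 0.2, seed = 4)
  tt <- truth_to_tracks(tr)
  zc <- 2523.1 / 2
  pr <- vessel_profile(tt, rbind(c(zc - 60, 1260), c(zc + 60, 1260)),
                       bin_um = 4.928)
  ctr <- which.max(pr$v_max)
  expect_true(all(diff(pr$v_max[1:ctr]) >= -0.5))       # rising toward axis
  expect_true(all(diff(pr$v_max[ctr:nrow(pr)]) <= 0.5)) # falling after
})
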