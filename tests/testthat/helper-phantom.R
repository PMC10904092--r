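# Shared fixture builders. Everything is generated in code at test time;
# sizes are desk-scale so the whole suite stays inside its runtime budget.

# a small straight-tube geometry matching the default grid
tiny_geom <- function(...) make_vessel_tree("straight", ...)

# default native grid (128 x 128 at 19.712 um) and a reduced 64 x 64 one
grid_native <- function(n = 128L) list(nz = n, nx = n, spacing_um = 19.712)
grid_map <- function(n = 509L) list(nz = n, nx = n, spacing_um = 4.928)

# render a Gaussian echo at (z0, x0) um on an [n x n] native grid
gauss_frame <- function(z0, x0, sigma = c(40, 30), n = 128L, sp = 19.712,
                        amp = 1) {
  zg <- (seq_len(n) - 1) * sp
  xg <- (seq_len(n) - 1) * sp
  amp * exp(-outer((zg - z0)^2 / (2 * sigma[1]^2),
                   (xg - x0)^2 / (2 * sigma[2]^2), "+"))
}

# hand-built track: data.frame of consecutive frames
mk_track <- function(z, x, frame_rate = 1000, f0 = 1L) {
  new_track(data.frame(frame = f0 + seq_along(z) - 1L, z_um = z, x_um = x),
            frame_rate)
}

# straight-line track along x at constant z
line_track <- function(n = 10L, z = 49.28, x0 = 0, step = 4.928,
                       frame_rate = 1000) {
  mk_track(rep(z, n), x0 + (seq_len(n) - 1) * step, frame_rate)
}

# brute-force minimal-cost one-to-one assignment (for <= 6 points):
# enumerates all injective mappings of rows to columns incl. non-assignment
# at cost gate^2 per unmatched point
brute_link_cost <- function(p1, p2, gate_um) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  g2 <- gate_um^2
  d2 <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2
  best <- Inf
  # assignments: each row of p1 gets a column of p2 or 0 (unmatched)
  opts <- c(0L, seq_len(n2))
  grid <- do.call(expand.grid, rep(list(opts), n1))
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    used <- a[a > 0]
    if (anyDuplicated(used)) next
    cost <- 0
    ok <- TRUE
    for (i in seq_len(n1)) {
      if (a[i] == 0L) cost <- cost + g2
      else if (d2[i, a[i]] > g2) { ok <- FALSE; break }
      else cost <- cost + d2[i, a[i]]
    }
    if (!ok) next
    cost <- cost + g2 * (n2 - length(used))
    if (cost < best) best <- cost
  }
  best
}

# cost actually realized by a link_frames() pairing
pairing_cost <- function(p1, p2, pairing, gate_um) {
  g2 <- gate_um^2
  cost <- 0
  if (nrow(pairing)) {
    for (r in seq_len(nrow(pairing))) {
      i <- pairing$i[r]; j <- pairing$j[r]
      cost <- cost + (p1[i, 1] - p2[j, 1])^2 + (p1[i, 2] - p2[j, 2])^2
    }
  }
  unname(cost + g2 * (nrow(p1) - nrow(pairing)) + g2 * (nrow(p2) - nrow(pairing)))
}

# match recovered tracks to ground-truth bubbles over shared frames;
# returns data.frame(track, bubble, mean_dist_um, truth_speed)
match_tracks_to_truth <- function(tracks, truth) {
  by_b <- split(truth, truth$bubble_id)
  out <- lapply(seq_along(tracks), function(ti) {
    t <- tracks[[ti]]
    best <- list(b = NA_integer_, d = Inf, sp = NA_real_)
    for (b in by_b) {
      shared <- intersect(t$frame, b$frame)
      if (length(shared) < nrow(t) / 2) next
      ti2 <- t[match(shared, t$frame), ]
      bi <- b[match(shared, b$frame), ]
      d <- mean(sqrt((ti2$z_um - bi$z_um)^2 + (ti2$x_um - bi$x_um)^2))
      if (d < best$d) best <- list(b = b$bubble_id[1], d = d, sp = b$speed_mms[1])
    }
    data.frame(track = ti, bubble = best$b, mean_dist_um = best$d,
               truth_speed = best$sp)
  })
  do.call(rbind, out)
}

# hand step-up BH oracle (independent of bh_adjust's cummin shortcut)
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- ps[i:m] * m / (i:m)
    adj[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
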