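# Frame-to-frame linking as a linear assignment problem (LAP). Localizations
# in frame t and t+1 are matched one-to-one, minimizing total squared
# distance, with a non-assignment alternative at cost gate^2 so that bubbles
# may appear or disappear. A simple, exactly specifiable stand-in for
# gap-closing trackers: no gaps, no merging, no splitting.

# Hungarian algorithm (shortest augmenting path with potentials, O(n^3));
# `cost` must be a finite square matrix. Returns, per row, the assigned
# column. Deterministic: rows are processed in index order, which also fixes
# the tie-break (earliest row/column wins among equal-cost assignments).
.hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) {
          minv[j + 1] <- cur
          way[j + 1] <- j0
        }
        if (minv[j + 1] < delta) {
          delta <- minv[j + 1]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_row <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) assign_row[p[j + 1]] <- j
  assign_row
}

#' Link localizations between two consecutive frames
#'
#' One-to-one assignment minimizing total squared distance among candidate
#' pairs within the gate; every localization also has a non-assignment
#' alternative at cost `gate_um^2` (an augmented square LAP), so unmatched
#' localizations simply start or terminate tracks.
#'
#' @param locs_t,locs_t1 data.frames with columns `z_um`, `x_um` (frame t and
#'   t+1); either may be empty.
#' @param gate_um maximum linking distance in micrometres (> 0).
#' @return data.frame with columns `i` (row in `locs_t`) and `j` (row in
#'   `locs_t1`) for matched pairs; zero rows if nothing links.
#' @export
link_frames <- function(locs_t, locs_t1, gate_um) {
  if (gate_um <= 0) stop("gate must be positive")
  n1 <- nrow(locs_t)
  n2 <- nrow(locs_t1)
  empty <- data.frame(i = integer(), j = integer())
  if (n1 == 0 || n2 == 0) return(empty)
  d2 <- outer(locs_t$z_um, locs_t1$z_um, "-")^2 +
        outer(locs_t$x_um, locs_t1$x_um, "-")^2
  g2 <- gate_um^2
  BIG <- 4 * g2 + max(d2[d2 <= g2], 0) + 1
  n <- n1 + n2
  C <- matrix(BIG, n, n)
  Cd <- d2
  Cd[Cd > g2] <- BIG
  C[seq_len(n1), seq_len(n2)] <- Cd
  for (i in seq_len(n1)) C[i, n2 + i] <- g2          # i unmatched
  for (j in seq_len(n2)) C[n1 + j, j] <- g2          # j unmatched
  C[(n1 + 1):n, (n2 + 1):n] <- 0                     # dummy-dummy
  a <- .hungarian(C)
  i <- seq_len(n1)
  j <- a[i]
  keep <- j <= n2 & d2[cbind(i, pmin(j, n2))] <= g2
  data.frame(i = i[keep], j = j[keep])
}

#' Assemble microbubble tracks from per-frame localizations
#'
#' Repeated [link_frames()] over consecutive frames. A track is a maximal
#' chain of linked localizations over strictly consecutive frames; a missed
#' frame terminates the chain (no gap closing). Tracks shorter than
#' `min_len` centroids are discarded, and per-step velocity vectors are
#' attached (`v = displacement_um * frame_rate / 1000` in mm/s).
#'
#' @param locs data.frame `(frame, z_um, x_um, ...)` for the whole stack.
#' @param frame_rate frames per second (> 0).
#' @param gate_um linking gate in micrometres; the default 30 um covers a
#'   20 mm/s bubble at 1 kHz with 50% margin.
#' @param min_len minimum track length in frames (centroids); default 10.
#' @return list of `ulm_track` objects. Each is a data.frame
#'   `(frame, z_um, x_um)` with attributes `vz_mms`, `vx_mms`,
#'   `speed_mms` (per-step), `mean_speed_mms` and `frame_rate`.
#' @export
build_tracks <- function(locs, frame_rate, gate_um = 30, min_len = 10L) {
  if (frame_rate <= 0) stop("frame rate must be positive")
  if (!nrow(locs)) return(list())
  locs <- locs[order(locs$frame), , drop = FALSE]
  frames <- sort(unique(locs$frame))
  by_frame <- split(locs, locs$frame)
  done <- list()
  # active chains: list of integer vectors of row indices into `locs`
  rows_of <- split(seq_len(nrow(locs)), locs$frame)
  active <- lapply(rows_of[[as.character(frames[1])]], function(r) r)
  for (k in seq_along(frames)[-1]) {
    consecutive <- frames[k] == frames[k - 1] + 1
    cur_rows <- rows_of[[as.character(frames[k])]]
    cur <- by_frame[[as.character(frames[k])]]
    if (!consecutive || length(active) == 0) {
      done <- c(done, active)
      active <- lapply(cur_rows, function(r) r)
      next
    }
    last_rows <- vapply(active, function(ch) ch[length(ch)], integer(1))
    prev <- locs[last_rows, , drop = FALSE]
    pairing <- link_frames(prev, cur, gate_um)
    matched_new <- logical(length(cur_rows))
    extended <- logical(length(active))
    if (nrow(pairing)) {
      for (r in seq_len(nrow(pairing))) {
        ci <- pairing$i[r]
        active[[ci]] <- c(active[[ci]], cur_rows[pairing$j[r]])
        extended[ci] <- TRUE
        matched_new[pairing$j[r]] <- TRUE
      }
    }
    done <- c(done, active[!extended])
    active <- c(active[extended],
                lapply(cur_rows[!matched_new], function(r) r))
  }
  done <- c(done, active)
  done <- done[lengths(done) >= min_len]
  lapply(done, function(ch) {
    pts <- locs[ch, c("frame", "z_um", "x_um")]
    rownames(pts) <- NULL
    new_track(pts, frame_rate)
  })
}

#' Construct a track object
#'
#' @param pts data.frame `(frame, z_um, x_um)` with strictly consecutive
#'   frames.
#' @param frame_rate frames per second.
#' @return object of class `ulm_track`.
#' @export
new_track <- function(pts, frame_rate) {
  if (nrow(pts) >= 2 && any(diff(pts$frame) != 1))
    stop("track frames must be strictly consecutive")
  dz <- diff(pts$z_um)
  dx <- diff(pts$x_um)
  vz <- dz * frame_rate / 1000
  vx <- dx * frame_rate / 1000
  sp <- sqrt(vz^2 + vx^2)
  structure(pts, class = c("ulm_track", "data.frame"),
            vz_mms = vz, vx_mms = vx, speed_mms = sp,
            mean_speed_mms = if (length(sp)) mean(sp) else NA_real_,
            frame_rate = frame_rate)
}

#' @export
print.ulm_track <- function(x, ...) {
  cat(sprintf("<ulm_track> %d centroids, frames %d-%d, mean speed %.3g mm/s\n",
              nrow(x), min(x$frame), max(x$frame), attr(x, "mean_speed_mms")))
  invisible(x)
}

#' Mean track speed
#'
#' Per-step speed is the Euclidean step length (um) times the frame rate,
#' divided by 1000 (mm/s); the track speed is the mean over steps.
#'
#' @param track an `ulm_track` or a data.frame `(frame, z_um, x_um)`.
#' @param frame_rate frames per second (defaults to the track's attribute).
#' @return speed in mm/s.
#' @export
track_speed <- function(track, frame_rate = NULL) {
  if (is.null(frame_rate)) frame_rate <- attr(track, "frame_rate")
  if (is.null(frame_rate)) stop("frame_rate required")
  if (nrow(track) < 2) stop("single-point track has no speed")
  steps <- sqrt(diff(track$z_um)^2 + diff(track$x_um)^2)
  mean(steps) * frame_rate / 1000
}

#' Flatten tracks to a tidy table
#'
#' @param tracks list of `ulm_track`.
#' @return data.frame `(track_id, frame, z_um, x_um, vz_mms, vx_mms)`;
#'   per-step velocities are repeated on the step's first centroid and `NA`
#'   on the last.
#' @export
tracks_to_df <- function(tracks) {
  if (!length(tracks))
    return(data.frame(track_id = integer(), frame = integer(),
                      z_um = numeric(), x_um = numeric(),
                      vz_mms = numeric(), vx_mms = numeric()))
  out <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(track_id = i, frame = tr$frame, z_um = tr$z_um, x_um = tr$x_um,
               vz_mms = c(attr(tr, "vz_mms"), NA),
               vx_mms = c(attr(tr, "vx_mms"), NA))
  }))
  rownames(out) <- NULL
  out
}
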