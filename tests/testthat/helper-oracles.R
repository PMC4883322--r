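# Independent brute-force oracles. These deliberately re-derive results by
# direct enumeration or plain loops, sharing no code with the implementation
# paths they check.

# 8-connected components by breadth-first flood fill over a logical mask
flood_fill8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r, c)); lab[r, c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# greedy ascending-distance one-to-one matching, re-derived with explicit
# data-frame bookkeeping (ties: lower track id, then lower region index)
oracle_greedy_match <- function(track_pos, track_ids, region_pos, max_dist) {
  if (nrow(track_pos) == 0 || nrow(region_pos) == 0)
    return(data.frame(track_id = integer(), region = integer()))
  cand <- expand.grid(t = seq_len(nrow(track_pos)),
                      r = seq_len(nrow(region_pos)))
  cand$d <- sqrt((track_pos[cand$t, 1] - region_pos[cand$r, 1])^2 +
                 (track_pos[cand$t, 2] - region_pos[cand$r, 2])^2)
  cand <- cand[cand$d <= rep_len(max_dist, nrow(track_pos))[cand$t], ]
  out <- data.frame(track_id = integer(), region = integer())
  while (nrow(cand)) {
    best <- cand[order(cand$d, track_ids[cand$t], cand$r)[1], ]
    out <- rbind(out, data.frame(track_id = track_ids[best$t],
                                 region = best$r))
    cand <- cand[cand$t != best$t & cand$r != best$r, ]
  }
  out[order(out$track_id), , drop = FALSE]
}

# five-feature descriptor by plain loops over the two tracks
oracle_features <- function(episode, ta, tb, fps) {
  speeds <- c()
  for (t in list(ta, tb)) {
    for (i in seq_len(length(t$frames) - 1)) {
      f0 <- t$frames[i]; f1 <- t$frames[i + 1]
      if (f0 >= episode$start_frame && f1 <= episode$end_frame) {
        d <- sqrt((t$rows[i + 1] - t$rows[i])^2 +
                  (t$cols[i + 1] - t$cols[i])^2)
        speeds <- c(speeds, d / (f1 - f0) * fps)
      }
    }
  }
  dists <- c()
  for (f in episode$start_frame:episode$end_frame) {
    ia <- which(ta$frames == f); ib <- which(tb$frames == f)
    if (length(ia) && length(ib))
      dists <- c(dists, sqrt((ta$rows[ia] - tb$rows[ib])^2 +
                             (ta$cols[ia] - tb$cols[ib])^2))
  }
  list(v_min = min(speeds), v_max = max(speeds), v_mean = mean(speeds),
       v_std = sqrt(sum((speeds - mean(speeds))^2) / length(speeds)),
       dist = mean(dists))
}

# minimal track structure for hand-built scenarios
mk_track <- function(id, frames, rows, cols, merged = NULL) {
  structure(list(id = as.integer(id), frames = as.integer(frames),
                 rows = rows, cols = cols,
                 merged = if (is.null(merged)) rep(FALSE, length(frames))
                          else merged),
            class = "pig_track")
}

# deterministic label permutation that leaves the caller's RNG alone
with_seed_shuffle <- function(labels, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(labels)
}

# tiny config for fast rendered-episode tests: full-size arena, short clips
fast_sim_config <- function(...) {
  sim_config(contact_s = c(1.2, 1.4), ...)
}
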