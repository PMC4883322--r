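meta30 <- sequence_meta(fps = 30)

test_that("single region within threshold keeps its track id", {
  m <- match_regions(rbind(c(10, 10)), 1L, rbind(c(12, 10)), max_dist_px = 20)
  expect_equal(m$assignment$track_id, 1L)
  expect_equal(m$assignment$region, 1L)
  expect_length(m$new_regions, 0)
})

test_that("a region beyond the threshold opens a new track", {
  m <- match_regions(rbind(c(10, 10)), 1L, rbind(c(80, 80)), max_dist_px = 20)
  expect_equal(nrow(m$assignment), 0)
  expect_equal(m$new_regions, 1L)
})

test_that("greedy matching picks the global-minimum pairing on the
           two-track crossing instance", {
  tpos <- rbind(c(0, 0), c(10, 0))
  rpos <- rbind(c(2, 0), c(9, 0))
  # oracle: enumerate both one-to-one assignments, take the cheaper
  straight <- sqrt(sum((tpos[1, ] - rpos[1, ])^2)) +
              sqrt(sum((tpos[2, ] - rpos[2, ])^2))   # 2 + 1 = 3
  crossed <- sqrt(sum((tpos[1, ] - rpos[2, ])^2)) +
             sqrt(sum((tpos[2, ] - rpos[1, ])^2))    # 9 + 8 = 17
  expect_lt(straight, crossed)
  m <- match_regions(tpos, c(1L, 2L), rpos, max_dist_px = 20)
  got <- m$assignment[order(m$assignment$track_id), ]
  expect_equal(got$region, c(1L, 2L))                # (0,0)->(2,0), (10,0)->(9,0)
})

test_that("greedy matching agrees with a brute-force re-derivation on
           random instances", {
  set.seed(13)
  for (trial in 1:200) {
    nt <- sample(0:5, 1); nr <- sample(0:5, 1)
    tpos <- matrix(runif(2 * nt, 0, 100), nt, 2)
    rpos <- matrix(runif(2 * nr, 0, 100), nr, 2)
    ids <- sample.int(50, nt)
    maxd <- runif(1, 10, 60)
    got <- match_regions(tpos, ids, rpos, maxd)$assignment
    got <- got[order(got$track_id), c("track_id", "region")]
    want <- oracle_greedy_match(tpos, ids, rpos, maxd)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("speeds follow displacement times frame rate", {
  still <- mk_track(1, 0:9, rep(5, 10), rep(5, 10))
  expect_true(all(compute_speeds(still, meta30)$speed_px_s == 0))

  mover <- mk_track(1, 0:4, rep(0, 5), seq(0, 12, by = 3))
  expect_equal(compute_speeds(mover, meta30)$speed_px_s, rep(90, 4))

  # displacement (3,4) over a 2-frame gap: 5 px * 30/2 = 75 px/s
  gap <- mk_track(1, c(0, 2), c(0, 3), c(0, 4))
  expect_equal(compute_speeds(gap, meta30)$speed_px_s, 75)

  short <- mk_track(1, 0, 1, 1)
  expect_equal(nrow(compute_speeds(short, meta30)), 0)
})

test_that("speeds convert to cm/s when the ground-plane scale is known", {
  m <- sequence_meta(fps = 30, px_per_cm = 3)
  tr <- mk_track(1, 0:1, c(0, 0), c(0, 3))
  sp <- compute_speeds(tr, m)
  expect_equal(sp$speed_px_s, 90)
  expect_equal(sp$speed_cm_s, 30)
})

test_that("speeds are invariant under global translation", {
  set.seed(5)
  for (trial in 1:20) {
    n <- sample(3:8, 1)
    rows <- cumsum(rnorm(n)); cols <- cumsum(rnorm(n))
    t1 <- mk_track(1, seq_len(n) - 1, rows, cols)
    t2 <- mk_track(1, seq_len(n) - 1, rows + 57.3, cols - 211.9)
    expect_equal(compute_speeds(t1, meta30), compute_speeds(t2, meta30))
  }
})

# synthetic region lists for sequence-level tracking tests
blob_regions <- function(centers, area = 100) {
  lapply(seq_len(nrow(centers)), function(i)
    structure(list(barycenter = c(row = centers[i, 1], col = centers[i, 2]),
                   area = area), class = "pig_region"))
}

test_that("a track deactivates after max_gap misses and a newcomer gets a
           fresh id", {
  seq_regions <- c(
    list(blob_regions(rbind(c(10, 10)))),
    replicate(7, list(), simplify = FALSE),          # 7 > max_gap misses
    list(blob_regions(rbind(c(12, 10)))))            # near old spot, too late
  tracks <- track_regions(seq_regions, max_dist_px = 30, max_gap = 5)
  expect_length(tracks, 2)
  expect_equal(sort(vapply(tracks, `[[`, integer(1), "id")), c(1L, 2L))
})

test_that("a short dropout within max_gap keeps the identity", {
  seq_regions <- c(
    list(blob_regions(rbind(c(10, 10)))),
    replicate(3, list(), simplify = FALSE),
    list(blob_regions(rbind(c(14, 10)))))
  tracks <- track_regions(seq_regions, max_dist_px = 30, max_gap = 5)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$frames, c(0L, 4L))
})

test_that("two tracks joining one large blob are both carried and flagged
           merged", {
  # two pigs approach, then one big region replaces both
  seq_regions <- list(
    blob_regions(rbind(c(50, 40), c(50, 80)), area = 1000),
    blob_regions(rbind(c(50, 42), c(50, 78)), area = 1000),
    blob_regions(rbind(c(50, 60)), area = 2000),
    blob_regions(rbind(c(50, 60)), area = 2000),
    blob_regions(rbind(c(50, 44), c(50, 76)), area = 1000))
  tracks <- track_regions(seq_regions, max_dist_px = 30, max_gap = 5)
  expect_length(tracks, 2)
  for (t in tracks) {
    expect_equal(t$frames, 0:4)                    # no identity break
    expect_equal(t$merged, c(FALSE, FALSE, TRUE, TRUE, FALSE))
    expect_equal(t$rows[3], 50); expect_equal(t$cols[3], 60)
  }
})

test_that("tracker recovers ground-truth identities exactly on rendered
           well-separated trajectories", {
  ep <- simulate_episode("walk_together", fast_sim_config(), seed = 101)
  pr <- process_sequence(ep$frames, ep$meta)
  expect_length(pr$tracks, 2)
  truth <- ep$truth$tracks
  # every frame of every ground-truth pig is covered by exactly one track,
  # and the pig -> track mapping never changes
  for (pig in unique(truth$pig)) {
    tp <- truth[truth$pig == pig, ]
    owner <- vapply(seq_len(nrow(tp)), function(i) {
      hits <- vapply(pr$tracks, function(t) {
        j <- match(tp$frame[i], t$frames)
        !is.na(j) && sqrt((t$rows[j] - tp$row[i])^2 +
                          (t$cols[j] - tp$col[i])^2) < 5
      }, logical(1))
      expect_equal(sum(hits), 1)
      which(hits)
    }, integer(1))
    expect_length(unique(owner), 1)
  }
})

test_that("the tracks table carries one speed per step and the merge flag", {
  tr <- list(mk_track(1, 0:2, c(0, 0, 0), c(0, 1, 2)))
  df <- tracks_to_df(tr, meta30)
  expect_equal(nrow(df), 3)
  expect_true(is.na(df$speed_px_s[1]))
  expect_equal(df$speed_px_s[-1], c(30, 30))
  expect_false(any(df$merged_flag))
})
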