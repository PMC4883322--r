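meta30 <- sequence_meta(fps = 30)

ep_row <- function(a, b, s, e)
  data.frame(episode_id = 1L, track_a = a, track_b = b,
             start_frame = s, end_frame = e)

test_that("stationary pigs give an all-zero velocity profile", {
  n <- 30
  tr <- list(mk_track(1, 0:(n - 1), rep(0, n), rep(0, n)),
             mk_track(2, 0:(n - 1), rep(50, n), rep(0, n)))
  fv <- extract_features(ep_row(1, 2, 0, n - 1), tr, meta30)
  expect_equal(c(fv$v_min, fv$v_max, fv$v_mean, fv$v_std), rep(0, 4))
  expect_equal(fv$dist, 50)
})

test_that("constant motion gives a degenerate spread", {
  n <- 20  # both pigs at 3 px/frame -> 90 px/s, 50 px apart
  tr <- list(mk_track(1, 0:(n - 1), rep(0, n), 3 * (0:(n - 1))),
             mk_track(2, 0:(n - 1), rep(50, n), 3 * (0:(n - 1))))
  fv <- extract_features(ep_row(1, 2, 0, n - 1), tr, meta30)
  expect_equal(fv$v_min, 90); expect_equal(fv$v_max, 90)
  expect_equal(fv$v_mean, 90); expect_equal(fv$v_std, 0)
  expect_equal(fv$dist, 50)
})

test_that("pooled statistics use the population standard deviation", {
  # pig A step speeds {0, 60}, pig B {30, 30}: pooled {0, 60, 30, 30},
  # population SD = sqrt(450) = 21.2132...
  ta <- mk_track(1, 0:2, c(0, 0, 0), c(0, 0, 2))
  tb <- mk_track(2, 0:2, c(40, 40, 40), c(0, 1, 2))
  fv <- extract_features(ep_row(1, 2, 0, 2), list(ta, tb), meta30)
  expect_equal(fv$v_min, 0)
  expect_equal(fv$v_max, 60)
  expect_equal(fv$v_mean, 30)
  expect_equal(fv$v_std, sqrt(450), tolerance = 1e-12)
  # distance: mean of the three per-frame barycenter distances
  expect_equal(fv$dist, mean(c(40, sqrt(40^2 + 1), sqrt(40^2 + 0))))
})

test_that("feature extraction matches a brute-force loop recomputation on
           randomized episodes", {
  set.seed(17)
  for (trial in 1:300) {
    n <- 10
    ta <- mk_track(1, 0:(n - 1), cumsum(rnorm(n, 0, 2)),
                   cumsum(rnorm(n, 0, 2)))
    tb <- mk_track(2, 0:(n - 1), 30 + cumsum(rnorm(n, 0, 2)),
                   cumsum(rnorm(n, 0, 2)))
    s <- sample(0:4, 1); e <- sample(5:9, 1)
    fv <- extract_features(ep_row(1, 2, s, e), list(ta, tb), meta30)
    want <- oracle_features(list(start_frame = s, end_frame = e), ta, tb, 30)
    expect_equal(fv$v_min, want$v_min)
    expect_equal(fv$v_max, want$v_max)
    expect_equal(fv$v_mean, want$v_mean)
    expect_equal(fv$v_std, want$v_std)
    expect_equal(fv$dist, want$dist)
  }
})

test_that("features are translation-invariant and scale-equivariant", {
  set.seed(19)
  n <- 12
  ta <- mk_track(1, 0:(n - 1), cumsum(rnorm(n)), cumsum(rnorm(n)))
  tb <- mk_track(2, 0:(n - 1), 20 + cumsum(rnorm(n)), cumsum(rnorm(n)))
  shift <- function(t, dr, dc) mk_track(t$id, t$frames, t$rows + dr,
                                        t$cols + dc)
  zoom <- function(t, k) mk_track(t$id, t$frames, t$rows * k, t$cols * k)
  base <- extract_features(ep_row(1, 2, 0, n - 1), list(ta, tb), meta30)
  moved <- extract_features(ep_row(1, 2, 0, n - 1),
                            list(shift(ta, 101, -44), shift(tb, 101, -44)),
                            meta30)
  for (f in c("v_min", "v_max", "v_mean", "v_std", "dist"))
    expect_equal(moved[[f]], base[[f]])
  scaled <- extract_features(ep_row(1, 2, 0, n - 1),
                             list(zoom(ta, 2.5), zoom(tb, 2.5)), meta30)
  for (f in c("v_min", "v_max", "v_mean", "v_std", "dist"))
    expect_equal(scaled[[f]], 2.5 * base[[f]])
})

test_that("speeds and distances report in cm when calibrated", {
  m <- sequence_meta(fps = 30, px_per_cm = 2)
  n <- 10
  tr <- list(mk_track(1, 0:(n - 1), rep(0, n), 2 * (0:(n - 1))),
             mk_track(2, 0:(n - 1), rep(60, n), 2 * (0:(n - 1))))
  fv <- extract_features(ep_row(1, 2, 0, n - 1), tr, m)
  expect_equal(fv$v_mean, 30)   # 60 px/s -> 30 cm/s
  expect_equal(fv$dist, 30)     # 60 px -> 30 cm
})

test_that("an episode shorter than two frames is rejected", {
  tr <- pairlist <- list(mk_track(1, 0:5, rep(0, 6), 0:5),
                         mk_track(2, 0:5, rep(9, 6), 0:5))
  expect_error(extract_features(ep_row(1, 2, 3, 3), tr, meta30),
               "insufficient")
})

test_that("feature tables round-trip through CSV", {
  expect_equal(nrow(features_to_table(list())), 0)
  n <- 10
  tr <- list(mk_track(1, 0:(n - 1), cumsum(rnorm(n)), cumsum(rnorm(n))),
             mk_track(2, 0:(n - 1), 25 + cumsum(rnorm(n)), cumsum(rnorm(n))))
  fvs <- lapply(1:3, function(i) {
    f <- extract_features(ep_row(1, 2, 0, n - 1), tr, meta30)
    f$episode_id <- i
    f
  })
  tab <- features_to_table(fvs)
  expect_equal(dim(tab), c(3, 7))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  back <- utils::read.csv(path)
  for (col in c("v_min", "v_max", "v_mean", "v_std", "dist"))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-6)
})
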