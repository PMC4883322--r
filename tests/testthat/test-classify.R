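rbf35 <- kernel_spec("rbf", C = 4.5, gamma = 3.5)
poly45 <- kernel_spec("polynomial", C = 4.5)

test_that("kernel evaluation matches its closed forms", {
  set.seed(3)
  for (trial in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(kernel_eval(rbf35, x, x), 1)
    expect_equal(kernel_eval(rbf35, x, y), kernel_eval(rbf35, y, x))
    k <- kernel_eval(rbf35, x, y)
    expect_true(k > 0 && k <= 1)
  }
  # unit squared distance at gamma = 3.5: exp(-3.5)
  x <- c(0, 0, 0, 0, 0); y <- c(1, 0, 0, 0, 0)
  expect_equal(kernel_eval(rbf35, x, y), exp(-3.5))
  expect_equal(kernel_eval(rbf35, x, y), 0.0301974, tolerance = 1e-6)
  # polynomial: orthogonal vectors, coef0 1, degree 3 -> 1
  expect_equal(kernel_eval(kernel_spec("polynomial", degree = 3, coef0 = 1),
                           c(1, 0), c(0, 1)), 1)
  expect_error(kernel_eval(rbf35, 1:3, 1:4), "dimension")
})

test_that("kernel specifications validate their parameters", {
  expect_error(kernel_spec("rbf", C = 0), "C")
  expect_error(kernel_spec("rbf", gamma = -1), "gamma")
  expect_error(kernel_spec("polynomial", degree = 0), "degree")
})

test_that("a separable problem is fit perfectly and single-class input
           errors", {
  x <- matrix(c(0, 0.5, 1, 9, 10, 11), ncol = 1)
  y <- factor(c("a", "a", "a", "b", "b", "b"))
  m <- train_svm(x, y, kernel_spec("polynomial", C = 100, degree = 1,
                                   coef0 = 0))
  expect_equal(as.character(predict(m, x)), as.character(y))
  expect_error(train_svm(x, factor(rep("a", 6), levels = c("a", "b")),
                         poly45),
               "both classes")
})

test_that("the RBF kernel separates the XOR pattern and agrees with an
           independent SVM implementation", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  x <- x[rep(1:4, 5), ] + matrix(rnorm(40, 0, 0.05), 20, 2)
  y <- factor(rep(c("p", "p", "q", "q"), 5))
  m <- train_svm(x, y, kernel_spec("rbf", C = 100, gamma = 3.5))
  expect_equal(as.character(predict(m, x)), as.character(y))
  skip_if_not_installed("kernlab")
  # same standardized data, same kernel/C: an independent solver must agree
  xs <- scale(x)
  k2 <- kernlab::ksvm(xs, y, kernel = "rbfdot",
                      kpar = list(sigma = 3.5), C = 100, scaled = FALSE)
  expect_equal(as.character(kernlab::predict(k2, xs)),
               as.character(predict(m, x)))
})

test_that("hierarchical prediction short-circuits normal episodes and
           matches a two-step table lookup on a separable toy set", {
  set.seed(29)
  # three clusters in the 5-feature space
  centers <- list(normal = c(30, 60, 40, 10, 75),
                  knocking = c(5, 900, 200, 350, 55),
                  chasing = c(100, 250, 130, 20, 78))
  mk <- function(lbl, n) {
    x <- t(replicate(n, centers[[lbl]] + rnorm(5, 0, 3)))
    colnames(x) <- c("v_min", "v_max", "v_mean", "v_std", "dist")
    list(x = x, y = rep(lbl, n))
  }
  parts <- lapply(names(centers), mk, n = 15)
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  y <- unlist(lapply(parts, `[[`, "y"))
  s1 <- train_svm(x, factor(ifelse(y == "normal", "normal", "aggressive"),
                            levels = c("normal", "aggressive")), poly45)
  s2 <- train_svm(x[y != "normal", ],
                  factor(y[y != "normal"], levels = c("knocking", "chasing")),
                  rbf35)
  got <- predict_hierarchical(s1, s2, x)
  # brute-force two-step lookup per point
  want <- vapply(seq_len(nrow(x)), function(i) {
    step1 <- as.character(predict(s1, x[i, , drop = FALSE]))
    if (step1 == "normal") "normal"
    else as.character(predict(s2, x[i, , drop = FALSE]))
  }, character(1))
  expect_equal(as.character(got), want)
  expect_equal(as.character(got), y)   # toy set is separable
  # stage-2 never touches points ruled normal: corrupting it cannot change them
  s2_flipped <- train_svm(x[y != "normal", ],
                          factor(rev(y[y != "normal"]),
                                 levels = c("knocking", "chasing")), rbf35)
  got2 <- predict_hierarchical(s1, s2_flipped, x)
  expect_equal(as.character(got2[y == "normal"]),
               as.character(got[y == "normal"]))
})

mk_feature_df <- function(n_per, centers, sd = 3, seed = 1) {
  set.seed(seed)
  rows <- lapply(names(centers), function(lbl) {
    x <- t(replicate(n_per[[lbl]], centers[[lbl]] + rnorm(5, 0, sd)))
    df <- as.data.frame(x)
    names(df) <- c("v_min", "v_max", "v_mean", "v_std", "dist")
    df$label <- lbl
    df
  })
  df <- do.call(rbind, rows)
  cbind(episode_id = seq_len(nrow(df)), df)
}

toy_centers <- list(normal = c(30, 60, 40, 10, 75),
                    knocking = c(5, 900, 200, 350, 55),
                    chasing = c(100, 250, 130, 20, 78))

test_that("cross-validation is perfect on separable data and deterministic
           in its seed", {
  df <- mk_feature_df(list(normal = 30, knocking = 15, chasing = 15),
                      toy_centers, seed = 37)
  m1 <- cross_validate(df, 1, poly45, k = 10, seed = 5)
  expect_equal(m1$ADR, 100); expect_equal(m1$FPR, 0); expect_equal(m1$FNR, 0)
  m2 <- cross_validate(df, 2, rbf35, k = 10, seed = 5)
  expect_equal(m2$macro_precision, 100)
  expect_equal(m2$macro_recall, 100)
  # determinism: same dataset + seed -> identical pooled confusion
  again <- cross_validate(df, 1, poly45, k = 10, seed = 5)
  expect_identical(m1$confusion, again$confusion)
  # and the fold builder does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(cross_validate(df, 1, poly45, k = 10, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("a class smaller than k falls back to leave-one-out with a
           warning", {
  df <- mk_feature_df(list(normal = 12, knocking = 4, chasing = 4),
                      toy_centers, seed = 41)
  expect_warning(m <- cross_validate(df, 2, rbf35, k = 10, seed = 1),
                 "leave-one-out")
  expect_s3_class(m, "class_metrics")
})
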