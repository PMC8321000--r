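test_that("statistical features follow the defining formulas", {
  f <- stat_features(c(1, 2, 3))
  expect_equal(f[["mean"]], 2)
  expect_equal(f[["median"]], 2)
  expect_equal(f[["variance"]], 2 / 3) # population variance
  expect_equal(f[["sd"]], sqrt(2 / 3))

  fc <- stat_features(rep(7, 10))
  expect_equal(unname(fc), c(7, 7, 7, 0, 0))

  fm <- stat_features(c(2, 2, 3, 9))
  expect_equal(fm[["mode"]], 2)
  expect_equal(fm[["median"]], 2.5) # even count: mean of the two central
  expect_equal(fm[["mean"]], 4)
  expect_error(stat_features(numeric(0)), "empty")
})

test_that("feature vectors assemble in fixed order with the consistency bit", {
  v <- build_feature_vector(rep(7, 5), t = 1)
  expect_equal(unname(v), c(7, 7, 7, 0, 0, 1))
  expect_equal(names(v),
               c("mean", "median", "mode", "variance", "sd", "consistency"))
  v2 <- build_feature_vector(c(1, 2, 3), t = 0)
  expect_equal(unname(v2), c(2, 2, 1, 2 / 3, sqrt(2 / 3), 0)) # mode tie -> smallest
  expect_length(v2, 6L)
  expect_error(build_feature_vector(c(1, 2), t = 2), "t")

  # sd/variance coherence on random regions
  set.seed(66)
  for (i in 1:20) {
    v <- build_feature_vector(sample(0:255, sample(1:50, 1), replace = TRUE),
                              t = sample(0:1, 1))
    expect_equal(v[["sd"]], sqrt(v[["variance"]]))
    expect_true(all(v[c("mean", "median", "mode")] >= 0 &
                    v[c("mean", "median", "mode")] <= 255))
  }
})

test_that("the consistency bit traces centers across the slice window", {
  # four candidates on slice j; only the first re-occurs in j-1 and j+1
  centers_j <- data.frame(center_r = c(50, 80, 120, 160),
                          center_c = c(50, 90, 40, 150))
  prev <- data.frame(center_r = c(51, 200), center_c = c(50, 200))
  nxt <- data.frame(center_r = c(49, 10), center_c = c(51, 10))
  t <- vapply(seq_len(4), function(i)
    consistency_feature(centers_j[i, ], list(prev, nxt), match_radius = 3),
    integer(1))
  expect_equal(t, c(1L, 0L, 0L, 0L))

  # single-slice stack: empty search set
  expect_equal(consistency_feature(c(10, 10), list()), 0L)
  expect_equal(consistency_feature(c(10, 10), list(NULL, NULL)), 0L)

  # inclusive boundary: neighbour exactly at match_radius
  nb <- data.frame(center_r = 13, center_c = 10)
  expect_equal(consistency_feature(c(10, 10), list(nb), match_radius = 3), 1L)
  expect_equal(consistency_feature(c(10, 10), list(nb), match_radius = 2.99), 0L)
})

make_toy_training <- function(n = 20) {
  # class A: tight bright regions with consistency 1; class B: spread, t = 0
  x <- rbind(
    cbind(mean = rnorm(n, 200, 5), median = rnorm(n, 200, 5),
          mode = rnorm(n, 200, 5), variance = runif(n, 0, 4),
          sd = NA, consistency = 1),
    cbind(mean = rnorm(n, 120, 5), median = rnorm(n, 120, 5),
          mode = rnorm(n, 120, 5), variance = runif(n, 400, 900),
          sd = NA, consistency = 0))
  x[, "sd"] <- sqrt(x[, "variance"])
  list(x = x, y = rep(c("nodule", "non_nodule"), each = n))
}

test_that("a separable toy set is fit with 100% training accuracy", {
  set.seed(77)
  toy <- make_toy_training()
  model <- train_classifier(toy$x, toy$y)
  pred <- classify_candidates(model, toy$x)
  expect_equal(mean(pred == toy$y), 1)
  # determinism: re-classifying the same set reproduces the labels
  expect_identical(classify_candidates(model, toy$x), pred)
  expect_error(train_classifier(toy$x[1:20, ], rep("nodule", 20)),
               "single-class")
})

test_that("classification is invariant to candidate order and batch identity", {
  set.seed(78)
  toy <- make_toy_training()
  model <- train_classifier(toy$x, toy$y)
  perm <- sample(nrow(toy$x))
  expect_identical(classify_candidates(model, toy$x[perm, ]),
                   classify_candidates(model, toy$x)[perm])
  two <- toy$x[c(3, 3), ]
  expect_equal(length(unique(classify_candidates(model, two))), 1L)
})

test_that("consistency handling modes compose as documented", {
  set.seed(79)
  toy <- make_toy_training()
  model <- train_classifier(toy$x, toy$y)
  batch <- toy$x[sample(nrow(toy$x), 25), ]
  f <- classify_candidates(model, batch, mode = "feature")
  fl <- classify_candidates(model, batch, mode = "filter")
  b <- classify_candidates(model, batch, mode = "both")
  expect_true(all(fl[batch[, "consistency"] == 0] == "non_nodule"))
  survivors <- batch[, "consistency"] == 1
  expect_identical(b[survivors], f[survivors])
  expect_true(all(b[!survivors] == "non_nodule"))
})

test_that("classifier persistence round-trips the decision function exactly", {
  set.seed(80)
  toy <- make_toy_training()
  model <- train_classifier(toy$x, toy$y)
  f <- withr::local_tempfile(fileext = ".json")
  save_classifier(model, f)
  back <- load_classifier(f)
  expect_equal(back$weights, model$weights)
  expect_equal(back$bias, model$bias)
  expect_equal(back$center, model$center)
  expect_equal(back$scale, model$scale)
  expect_identical(classify_candidates(back, toy$x),
                   classify_candidates(model, toy$x))
  expect_error(load_classifier({
    g <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(format = "other"), g)
    g
  }), "not a lungcad classifier")
})
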