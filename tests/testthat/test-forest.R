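test_that("training is deterministic given the seed", {
  task <- toy_task()
  m1 <- train_forest(task$x, task$y, n_trees = 30, seed = 5)
  m2 <- train_forest(task$x, task$y, n_trees = 30, seed = 5)
  p1 <- predict_votes(m1, task$x)
  p2 <- predict_votes(m2, task$x)
  expect_identical(p1$vote_fraction, p2$vote_fraction)
  m3 <- train_forest(task$x, task$y, n_trees = 30, seed = 6)
  p3 <- predict_votes(m3, task$x)
  expect_false(identical(p1$vote_fraction, p3$vote_fraction))
})

test_that("vote fractions are multiples of 1/n_trees in [0, 1]", {
  task <- toy_task()
  m <- train_forest(task$x, task$y, n_trees = 23, seed = 1)
  p <- predict_votes(m, task$x)
  expect_true(all(p$vote_fraction >= 0 & p$vote_fraction <= 1))
  expect_equal(p$vote_fraction * 23, round(p$vote_fraction * 23))
})

test_that("a one-class training set predicts that class everywhere", {
  task <- toy_task(n = 60)
  m <- train_forest(task$x, rep(0L, 60), n_trees = 15, seed = 2)
  p <- predict_votes(m, task$x)
  expect_true(all(p$vote_fraction == 0))
  expect_true(all(p$label == 0L))
  expect_equal(nrow(prediction_segments(p)), 0L)
})

test_that("out-of-bag error is small on the separable toy task", {
  task <- toy_task(n = 200)
  m <- train_forest(task$x, task$y, n_trees = 50, seed = 3)
  expect_lt(m$oob_error, 0.05)
})

test_that("more trees do not degrade OOB error beyond noise", {
  task <- toy_task(n = 200)
  m10 <- train_forest(task$x, task$y, n_trees = 10, seed = 4)
  m200 <- train_forest(task$x, task$y, n_trees = 200, seed = 4)
  expect_lte(m200$oob_error, m10$oob_error + 0.05)
})

test_that("with one tree, all features, and no bootstrap the forest reduces to a lone decision tree", {
  task <- toy_task(n = 120, p_noise = 2)
  m <- train_forest(task$x, task$y, n_trees = 1, m_features = 3, seed = 7,
                    bootstrap = FALSE)
  p <- predict_votes(m, task$x)
  # a purity-grown tree classifies its own noise-free training set perfectly
  expect_equal(p$label, task$y)
  expect_true(all(p$vote_fraction %in% c(0, 1)))
})

test_that("the vote threshold comparison is >= and min_linker_run filters short runs", {
  expect_equal(filter_min_run(c(0, 0, 1, 1, 1, 0, 1, 0), 2),
               c(0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(filter_min_run(c(1, 0, 1), 0), c(1L, 0L, 1L))

  task <- toy_task(n = 150)
  m <- train_forest(task$x, task$y, n_trees = 40, seed = 8)
  p <- predict_votes(m, task$x)
  # pick an attained interior vote fraction and re-threshold exactly at it:
  # a residue sitting exactly on the threshold must be called linker
  v0 <- sort(unique(p$vote_fraction[p$vote_fraction > 0 & p$vote_fraction < 1]))
  if (length(v0) > 0) {
    m2 <- train_forest(task$x, task$y, n_trees = 40, seed = 8,
                       vote_threshold = v0[1])
    p2 <- predict_votes(m2, task$x)
    expect_identical(p2$label, as.integer(p2$vote_fraction >= v0[1]))
    expect_true(any(p2$label[p2$vote_fraction == v0[1]] == 1L))
  }
  # labels are the thresholded votes; segments are the maximal label runs
  expect_identical(p$label, as.integer(p$vote_fraction >= 0.5))
  seg <- labels_to_segments(p$label)
  expect_equal(nrow(prediction_segments(p)), nrow(seg))
})

test_that("guards: empty features, bad m, mismatched profile names", {
  task <- toy_task(n = 30)
  expect_error(train_forest(task$x[, 0], task$y), "no columns")
  expect_error(train_forest(task$x, task$y, m_features = 99), "m_features")
  m <- train_forest(task$x, task$y, n_trees = 10, seed = 1)
  bad <- task$x
  colnames(bad) <- paste0("g", seq_len(ncol(bad)))
  expect_error(predict_votes(m, bad), "feature names")
})

test_that("models persist to file and restore identically", {
  task <- toy_task(n = 50)
  m <- train_forest(task$x, task$y, n_trees = 10, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".rds")
  write_forest(m, tmp)
  m2 <- read_forest(tmp)
  expect_identical(predict_votes(m, task$x)$vote_fraction,
                   predict_votes(m2, task$x)$vote_fraction)
  saveRDS(list(a = 1), tmp)
  expect_error(read_forest(tmp), "not a linkerforest model")
})

test_that("tidy and glance expose importance and hyperparameters", {
  task <- toy_task(n = 100)
  m <- train_forest(task$x, task$y, n_trees = 25, seed = 2)
  td <- tidy(m)
  expect_setequal(td$feature, colnames(task$x))
  # the signal feature dominates Gini importance
  expect_equal(td$feature[1], "f1")
  gl <- glance(m)
  expect_equal(gl$n_trees, 25)
  expect_equal(gl$m_features, floor(log2(5)) + 1)
})
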