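test_that("scoring matches direct confusion arithmetic", {
  truth <- c(rep(1, 10), rep(0, 90))
  pred <- c(rep(1, 7), rep(0, 3), rep(1, 1), rep(0, 89))
  sc <- score_predictions(truth, pred)
  expect_equal(sc$tp, 7); expect_equal(sc$fn, 3)
  expect_equal(sc$fp, 1); expect_equal(sc$tn, 89)
  expect_equal(sc$accuracy, 0.96)
  expect_equal(sc$recall, 0.7)
  expect_equal(sc$precision, 0.875)
  expect_equal(sc$f1, 2 * 0.7 * 0.875 / (0.7 + 0.875))
  expect_false(sc$zero_division)

  perfect <- score_predictions(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$recall, perfect$precision, perfect$f1),
               rep(1, 4))
})

test_that("scoring agrees with a brute-force per-residue oracle", {
  withr::with_seed(77, {
    for (i in 1:20) {
      lens <- sample(3:30, sample(1:4, 1), replace = TRUE)
      truth <- lapply(lens, function(L) as.integer(runif(L) < 0.3))
      pred <- lapply(lens, function(L) as.integer(runif(L) < 0.4))
      sc <- score_predictions(truth, pred)
      t <- unlist(truth); p <- unlist(pred)
      tp <- 0; tn <- 0; fp <- 0; fn <- 0
      for (j in seq_along(t)) {
        if (t[j] == 1 && p[j] == 1) tp <- tp + 1
        if (t[j] == 0 && p[j] == 0) tn <- tn + 1
        if (t[j] == 0 && p[j] == 1) fp <- fp + 1
        if (t[j] == 1 && p[j] == 0) fn <- fn + 1
      }
      expect_equal(c(sc$tp, sc$tn, sc$fp, sc$fn), c(tp, tn, fp, fn))
      expect_equal(sc$tp + sc$tn + sc$fp + sc$fn, length(t))
      # harmonic-mean identity of the reported P and R, to machine precision
      if (sc$precision + sc$recall > 0) {
        expect_equal(sc$f1, 2 * sc$precision * sc$recall / (sc$precision + sc$recall))
        if (sc$precision > 0 && sc$recall > 0) {
          expect_gte(sc$f1, min(sc$precision, sc$recall) - 1e-12)
          expect_lte(sc$f1, max(sc$precision, sc$recall) + 1e-12)
        }
      }
    }
  })
})

test_that("zero-denominator metrics report 0 with a flag", {
  sc <- score_predictions(c(0, 0, 0), c(0, 0, 0)) # no positives anywhere
  expect_equal(sc$recall, 0)
  expect_equal(sc$precision, 0)
  expect_equal(sc$f1, 0)
  expect_true(sc$zero_division)
  expect_error(score_predictions(c(0, 1), c(0, 1, 1)), "aligned")
})

test_that("information gain matches enumeration and its invariances", {
  # all 3 thresholds by hand: split at 2.5 is pure -> IG = H(y) = 1 bit
  expect_equal(information_gain(cbind(f = c(1, 2, 3, 4)),
                                c(0, 0, 1, 1))$info_gain, 1)
  # a feature identical to the labels attains H(y) exactly
  withr::with_seed(10, y <- as.integer(runif(400) < 0.3))
  hy <- {
    p <- mean(y); -(p * log2(p) + (1 - p) * log2(1 - p))
  }
  ig <- information_gain(cbind(same = as.numeric(y), junk = seq_along(y) %% 7), y)
  expect_equal(ig$info_gain[1], hy)
  # independence null: IG of a random feature is tiny at N = 1e4
  withr::with_seed(11, {
    yb <- as.integer(runif(1e4) < 0.5)
    xr <- rnorm(1e4)
  })
  expect_lt(information_gain(cbind(x = xr), yb)$info_gain, 0.01)
  # invariant under strictly monotone transformation
  withr::with_seed(12, {
    x <- rnorm(300)
    ym <- as.integer(x + rnorm(300, sd = 0.5) > 0)
  })
  ig1 <- information_gain(cbind(a = x), ym)$info_gain
  ig2 <- information_gain(cbind(a = exp(x)), ym)$info_gain
  expect_equal(ig1, ig2)
  # constant labels: all-zero IG with a warning
  expect_warning(ig0 <- information_gain(cbind(a = x), rep(1L, 300)), "constant")
  expect_equal(ig0$info_gain, 0)
})

test_that("cross-validation is deterministic, sequence-level, and pools counts", {
  corp <- make_corpus(12, seed = 3)
  cv1 <- cross_validate(corp, k = 3, n_trees = 20, window = 11, seed = 9,
                        pseudocount = 0.1)
  cv2 <- cross_validate(corp, k = 3, n_trees = 20, window = 11, seed = 9,
                        pseudocount = 0.1)
  expect_identical(cv1$assignment, cv2$assignment)
  expect_equal(cv1$per_fold, cv2$per_fold)
  # pooled counts are the sums of the per-fold counts
  expect_equal(cv1$pooled$tp, sum(cv1$per_fold$tp))
  expect_equal(cv1$pooled$tn, sum(cv1$per_fold$tn))
  expect_equal(cv1$pooled$fp, sum(cv1$per_fold$fp))
  expect_equal(cv1$pooled$fn, sum(cv1$per_fold$fn))
  # every residue of the corpus is scored exactly once
  expect_equal(cv1$pooled$tp + cv1$pooled$tn + cv1$pooled$fp + cv1$pooled$fn,
               sum(lengths(corp$labels)))
  # metrics live in [0, 1]
  with(cv1$per_fold, {
    expect_true(all(accuracy >= 0 & accuracy <= 1))
    expect_true(all(f1 >= 0 & f1 <= 1))
  })
  expect_error(cross_validate(corp, k = 1), "k must be")
  expect_error(cross_validate(corp, k = 13), "k must be")
})

test_that("k equal to the number of sequences gives leave-one-sequence-out", {
  corp <- make_corpus(6, seed = 4)
  cv <- cross_validate(corp, k = 6, n_trees = 10, window = 5, seed = 2,
                       pseudocount = 0.1)
  expect_equal(nrow(cv$per_fold), 6)
  expect_equal(sort(unique(cv$assignment)), 1:6)
  expect_equal(unname(table(cv$assignment)), rep(1L, 6), ignore_attr = TRUE)
})

test_that("window sweep reduces to a single cross-validation at one size", {
  corp <- make_corpus(8, seed = 6)
  sw <- sweep_window(corp, sizes = c(5, 9), subset_size = 8, k = 4,
                     n_trees = 10, seed = 3, pseudocount = 0.1)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$window, c(5, 9))
  cv <- cross_validate(corp, k = 4, window = 9, n_trees = 10, seed = 3,
                       pseudocount = 0.1)
  expect_equal(sw$f1[sw$window == 9], cv$fold_mean$f1)
  expect_error(sweep_window(corp, sizes = c(5, 8)), "odd")
  expect_error(sweep_window(corp, sizes = c(5, 5)), "duplicate")
  expect_error(sweep_window(corp, sizes = 5, subset_size = 99), "subset_size")
})

test_that("tree sweep validates its counts and returns one row per count", {
  corp <- make_corpus(8, seed = 8)
  sw <- sweep_trees(corp, tree_counts = c(10, 25), subset_size = 8, k = 4,
                    window = 7, seed = 3, pseudocount = 0.1)
  expect_equal(sw$n_trees, c(10, 25))
  expect_error(sweep_trees(corp, tree_counts = c(10, 10)), "duplicate")
  expect_error(sweep_trees(corp, tree_counts = c(5, 50)), "10, 500")
})

test_that("ablation starts from the unablated run and removes groups by ascending IG", {
  corp <- make_corpus(9, seed = 13)
  ab <- ablate_groups(corp, k = 3, window = 9, n_trees = 10, seed = 4,
                      pseudocount = 0.1)
  expect_s3_class(ab, "linker_ablation")
  # row 0 equals the plain cross-validated result under the same settings
  cv <- cross_validate(corp, k = 3, window = 9, n_trees = 10, seed = 4,
                       pseudocount = 0.1)
  expect_equal(ab$f1[1], cv$fold_mean$f1)
  expect_equal(ab$removed[1], "none")
  # 7 groups: baseline + 6 removals (stops before emptying the feature set)
  expect_equal(nrow(ab), 7)
  # removal order follows ascending group information gain
  gig <- attr(ab, "group_ig")
  expect_equal(ab$removed[-1], gig$group[1:6])
  expect_equal(sort(gig$info_gain), gig$info_gain)

  ab1 <- ablate_groups(corp, k = 3, window = 9, n_trees = 10, seed = 4,
                       pseudocount = 0.1, scheme = "single")
  expect_equal(nrow(ab1), 8) # baseline + one row per group
  expect_setequal(ab1$removed[-1], feature_group_names())
})
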