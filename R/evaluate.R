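#' F-measure from recall and precision
#'
#' The harmonic mean `2 P R / (P + R)`, returning 0 when both are 0.
#'
#' @param recall,precision Reals in \[0, 1\].
#' @return The F1 value.
#' @examples
#' f_measure(0.675, 0.987)
#' @export
f_measure <- function(recall, precision) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

eval_from_counts <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  safe <- function(num, den) if (den > 0) num / den else 0
  recall <- safe(tp, tp + fn)
  precision <- safe(tp, tp + fp)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = safe(tp + tn, total),
    recall = recall,
    precision = precision,
    f1 = f_measure(recall, precision),
    zero_division = (tp + fn == 0) || (tp + fp == 0)
  )
}

#' Score per-residue predictions against truth labels
#'
#' Pools the residue-level confusion counts over all sequences (linker = the
#' positive class) and reports accuracy, recall, precision, and F-measure.
#' Ratios with a zero denominator are reported as 0 with the
#' `zero_division` flag set, so downstream tables stay totals-safe.
#'
#' @param truth,predicted Binary label vectors, or lists of per-sequence
#'   binary vectors (aligned element-wise).
#' @return A one-row tibble of class `linker_eval`: `tp`, `tn`, `fp`, `fn`,
#'   `accuracy`, `recall`, `precision`, `f1`, `zero_division`.
#' @examples
#' score_predictions(c(0, 0, 1, 1, 0), c(0, 1, 1, 0, 0))
#' @export
score_predictions <- function(truth, predicted) {
  if (!is.list(truth)) truth <- list(truth)
  if (!is.list(predicted)) predicted <- list(predicted)
  if (length(truth) != length(predicted) ||
      !all(lengths(truth) == lengths(predicted))) {
    stop("truth and predicted must be aligned per sequence", call. = FALSE)
  }
  t <- as.integer(unlist(truth, use.names = FALSE))
  p <- as.integer(unlist(predicted, use.names = FALSE))
  out <- eval_from_counts(
    tp = sum(t == 1L & p == 1L), tn = sum(t == 0L & p == 0L),
    fp = sum(t == 0L & p == 1L), fn = sum(t == 1L & p == 0L)
  )
  class(out) <- c("linker_eval", class(out))
  out
}

fold_assignment <- function(n, k, seed) {
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# Resolve the composition/index table used for a training fold
fold_tables <- function(corpus_train, config, pseudocount) {
  if (config$linker_index_source == "estimated_from_training" &&
      "linker_index" %in% config$groups) {
    comp <- compute_linker_index(corpus_train, pseudocount = pseudocount)
    aa_property_tables(composition = comp)
  } else {
    aa_property_tables()
  }
}

#' Sequence-level k-fold cross-validation of the full pipeline
#'
#' Splits the corpus into `k` folds at the sequence level (never at the
#' residue level, which would leak windowed features between train and test).
#' For each fold: the linker-propensity index is re-estimated on the training
#' sequences (when `config$linker_index_source` is
#' `"estimated_from_training"`), windowed profiles are built, a forest is
#' trained, and the held-out sequences are scored per residue. Reports
#' per-fold metrics, their fold-means, and metrics pooled over all residues.
#'
#' @param corpus An annotated corpus (`seq_id`, `residues`, `labels`).
#' @param k Number of folds (default 10); `k = nrow(corpus)` gives
#'   leave-one-sequence-out.
#' @param config [encoding_config()].
#' @param window Odd averaging window, default 41.
#' @param n_trees,m_features,vote_threshold,min_linker_run Forest settings,
#'   see [train_forest()].
#' @param pseudocount Passed to [compute_linker_index()] for per-fold index
#'   estimation.
#' @param seed Controls the fold assignment and (offset per fold) the forest
#'   seeds.
#' @return An object of class `linker_cv`: list with `per_fold` (tibble, one
#'   row per fold), `pooled` (a `linker_eval`), `fold_mean` (one-row tibble
#'   of metric means), `assignment` (fold id per sequence), and `settings`.
#' @export
cross_validate <- function(corpus, k = 10, config = encoding_config(),
                           window = 41, n_trees = 200, m_features = "auto",
                           vote_threshold = 0.5, min_linker_run = 0L,
                           pseudocount = 0, seed = 1L) {
  n <- nrow(corpus)
  if (k < 2 || k > n) stop("k must be in 2..number of sequences", call. = FALSE)
  folds <- fold_assignment(n, k, seed)

  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    tabs <- fold_tables(corpus[train_idx, ], config, pseudocount)
    lut <- encoding_lut(tabs, config)

    prof_of <- function(i) {
      chars <- strsplit(corpus$residues[i], "")[[1]]
      window_average(lut[chars, , drop = FALSE], window)
    }
    x_train <- do.call(rbind, lapply(train_idx, prof_of))
    y_train <- unlist(corpus$labels[train_idx], use.names = FALSE)
    model <- train_forest(x_train, y_train, n_trees = n_trees,
                          m_features = m_features, seed = seed + f,
                          vote_threshold = vote_threshold,
                          min_linker_run = min_linker_run)
    x_test <- do.call(rbind, lapply(test_idx, prof_of))
    rownames(x_test) <- NULL
    pred <- predict_votes(model, x_test)
    truth <- unlist(corpus$labels[test_idx], use.names = FALSE)
    sc <- score_predictions(truth, pred$label)
    fold_rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), sc)
  }
  per_fold <- dplyr::bind_rows(fold_rows)
  pooled <- eval_from_counts(sum(per_fold$tp), sum(per_fold$tn),
                             sum(per_fold$fp), sum(per_fold$fn))
  class(pooled) <- c("linker_eval", class(pooled))
  fold_mean <- per_fold |>
    dplyr::summarise(dplyr::across(c("accuracy", "recall", "precision", "f1"), mean))

  structure(
    list(per_fold = per_fold, pooled = pooled, fold_mean = fold_mean,
         assignment = folds,
         settings = list(k = k, config = config, window = window,
                         n_trees = n_trees, m_features = m_features,
                         vote_threshold = vote_threshold,
                         min_linker_run = min_linker_run,
                         pseudocount = pseudocount, seed = seed)),
    class = "linker_cv"
  )
}

#' @export
print.linker_cv <- function(x, ...) {
  cat(sprintf("<linker_cv> %d-fold, window %d, %d trees\n",
              x$settings$k, x$settings$window, x$settings$n_trees))
  cat(sprintf("  fold-mean: R=%.3f P=%.3f F1=%.3f | pooled: R=%.3f P=%.3f F1=%.3f\n",
              x$fold_mean$recall, x$fold_mean$precision, x$fold_mean$f1,
              x$pooled$recall, x$pooled$precision, x$pooled$f1))
  invisible(x)
}

#' Per-fold cross-validation metrics
#' @param x A `linker_cv`.
#' @param ... Unused.
#' @return The per-fold tibble.
#' @export
tidy.linker_cv <- function(x, ...) x$per_fold

#' One-row cross-validation summary (fold means + pooled metrics)
#' @param x A `linker_cv`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.linker_cv <- function(x, ...) {
  tibble::tibble(
    k = x$settings$k, window = x$settings$window, n_trees = x$settings$n_trees,
    recall = x$fold_mean$recall, precision = x$fold_mean$precision,
    f1 = x$fold_mean$f1, accuracy = x$fold_mean$accuracy,
    pooled_recall = x$pooled$recall, pooled_precision = x$pooled$precision,
    pooled_f1 = x$pooled$f1
  )
}

draw_subset <- function(corpus, subset_size, seed) {
  if (subset_size > nrow(corpus)) {
    stop("subset_size exceeds corpus size", call. = FALSE)
  }
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  corpus[sort(sample(nrow(corpus), subset_size)), ]
}

#' Sweep the averaging window size
#'
#' Draws one seeded random subset of the corpus, then cross-validates once
#' per candidate window size and tabulates recall, precision, and F-measure
#' (fold means) per size. Used to locate the optimal window (41 on the
#' calibration datasets).
#'
#' @param corpus An annotated corpus.
#' @param sizes Odd window sizes, default `seq(7, 45, 2)`.
#' @param subset_size Sequences drawn for the sweep (default 50); must not
#'   exceed the corpus size.
#' @param k,config,n_trees,seed,... Passed to [cross_validate()].
#' @return A tibble of class `linker_sweep` with one row per size: `window`,
#'   `recall`, `precision`, `f1`, `accuracy`.
#' @export
sweep_window <- function(corpus, sizes = seq(7, 45, by = 2), subset_size = 50,
                         k = 10, config = encoding_config(), n_trees = 200,
                         seed = 1L, ...) {
  if (any(sizes %% 2 == 0) || any(sizes < 1)) {
    stop("window sizes must be odd positive integers", call. = FALSE)
  }
  if (anyDuplicated(sizes)) stop("duplicate window sizes", call. = FALSE)
  sub <- draw_subset(corpus, subset_size, seed)
  rows <- purrr::map(sizes, function(w) {
    cv <- cross_validate(sub, k = k, config = config, window = w,
                         n_trees = n_trees, seed = seed, ...)
    dplyr::bind_cols(tibble::tibble(window = w), cv$fold_mean)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "sweep") <- "window"
  class(out) <- c("linker_sweep", class(out))
  out
}

#' Sweep the number of trees
#'
#' Analogous to [sweep_window()]: one seeded subset, one cross-validation per
#' ensemble size.
#'
#' @param corpus An annotated corpus.
#' @param tree_counts Distinct tree counts in \[10, 500\].
#' @param subset_size,k,config,window,seed,... As in [sweep_window()] /
#'   [cross_validate()].
#' @return A tibble of class `linker_sweep` with one row per count.
#' @export
sweep_trees <- function(corpus, tree_counts = c(10, 50, 100, 200, 500),
                        subset_size = 50, k = 10, config = encoding_config(),
                        window = 41, seed = 1L, ...) {
  if (any(tree_counts < 10) || any(tree_counts > 500)) {
    stop("tree counts must lie in [10, 500]", call. = FALSE)
  }
  if (anyDuplicated(tree_counts)) stop("duplicate tree counts", call. = FALSE)
  sub <- draw_subset(corpus, subset_size, seed)
  rows <- purrr::map(tree_counts, function(nt) {
    cv <- cross_validate(sub, k = k, config = config, window = window,
                         n_trees = nt, seed = seed, ...)
    dplyr::bind_cols(tibble::tibble(n_trees = nt), cv$fold_mean)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "sweep") <- "n_trees"
  class(out) <- c("linker_sweep", class(out))
  out
}

#' Information gain of each feature for a binary label
#'
#' For every column of `x`, finds the single binary split threshold that
#' minimizes the weighted conditional label entropy and reports the entropy
#' reduction (C4.5-style best-split information gain) in bits:
#' `IG(f) = H(y) - min_t [ p(x<=t) H(y | x<=t) + p(x>t) H(y | x>t) ]`.
#' Values lie in `[0, H(y)]` and are invariant under strictly monotone
#' transformations of a feature.
#'
#' @param x N x M numeric matrix or data frame.
#' @param y Length-N binary labels.
#' @return A tibble with columns `feature`, `info_gain`, in column order.
#' @examples
#' information_gain(cbind(f = c(1, 2, 3, 4)), c(0, 0, 1, 1)) # 1 bit
#' @export
information_gain <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- length(y)
  stopifnot(nrow(x) == n, n >= 2)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  ent <- function(pos, tot) {
    # binary entropy in bits of a pos/tot split; 0 entropy for empty/pure
    p <- pos / tot
    h <- numeric(length(p))
    ok <- tot > 0 & p > 0 & p < 1
    h[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
    h
  }
  n_pos <- sum(y == 1L)
  h_y <- ent(n_pos, n)
  if (h_y == 0) {
    warning("labels are constant; all information gains are 0", call. = FALSE)
    return(tibble::tibble(feature = colnames(x), info_gain = 0))
  }
  ig <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    o <- order(v)
    vs <- v[o]; ys <- y[o]
    cum_pos <- cumsum(ys == 1L)
    # candidate split after position i (between distinct adjacent values)
    cand <- which(vs[-n] < vs[-1])
    if (length(cand) == 0L) return(0)
    nl <- cand
    hl <- ent(cum_pos[cand], nl)
    hr <- ent(n_pos - cum_pos[cand], n - nl)
    cond <- (nl * hl + (n - nl) * hr) / n
    max(h_y - min(cond), 0)
  }, numeric(1))
  tibble::tibble(feature = colnames(x), info_gain = ig)
}

#' Information gain aggregated to feature groups
#'
#' @param x N x M matrix with columns named as in [feature_names()].
#' @param y Binary labels.
#' @param group_map Named character vector mapping feature name to group, as
#'   from [feature_group_map()].
#' @return A tibble `group`, `info_gain` (mean member IG), ascending.
#' @export
group_information_gain <- function(x, y, group_map) {
  ig <- information_gain(x, y)
  ig$group <- unname(group_map[ig$feature])
  ig |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(info_gain = mean(.data$info_gain), .groups = "drop") |>
    dplyr::arrange(.data$info_gain)
}

#' Cumulative (or single-group) feature ablation ordered by information gain
#'
#' Ranks the seven feature groups by information gain measured on the full
#' corpus profile matrix, then re-runs the cross-validated pipeline while
#' removing groups. With `scheme = "cumulative"` (the default) groups are
#' removed one after another in ascending-IG order — the first row is the
#' unablated run, each later row has one more group removed — stopping
#' before the final group would leave the feature set empty. With
#' `scheme = "single"` each row removes exactly one group from the full set,
#' which isolates the marginal contribution of each group.
#'
#' @param corpus An annotated corpus.
#' @param k,config,window,n_trees,seed,pseudocount,... Passed to
#'   [cross_validate()].
#' @param scheme `"cumulative"` or `"single"`.
#' @return A tibble of class `linker_ablation`: `removed` (group removed at
#'   this step, `"none"` for the baseline), `removed_so_far` (comma-joined,
#'   cumulative scheme), `group_info_gain`, `recall`, `precision`, `f1`,
#'   `accuracy`.
#' @export
ablate_groups <- function(corpus, k = 10, config = encoding_config(),
                          window = 41, n_trees = 200, seed = 1L,
                          scheme = c("cumulative", "single"),
                          pseudocount = 0, ...) {
  scheme <- match.arg(scheme)
  # IG ranking on the full-corpus profile matrix (ranking only; the CV runs
  # below re-estimate everything per training fold)
  tabs <- fold_tables(corpus, config, pseudocount = pseudocount)
  lut <- encoding_lut(tabs, config)
  x <- do.call(rbind, lapply(corpus$residues, function(res) {
    window_average(lut[strsplit(res, "")[[1]], , drop = FALSE], window)
  }))
  y <- unlist(corpus$labels, use.names = FALSE)
  gmap <- feature_group_map(config)
  gig <- group_information_gain(x, y, gmap)

  run_cv <- function(groups_kept) {
    cfg <- encoding_config(
      hydrophobicity = config$hydrophobicity,
      categorical = config$categorical,
      use_linker_index = "linker_index" %in% groups_kept,
      linker_index_source = config$linker_index_source,
      groups = groups_kept
    )
    cv <- cross_validate(corpus, k = k, config = cfg, window = window,
                         n_trees = n_trees, seed = seed,
                         pseudocount = pseudocount, ...)
    cv$fold_mean
  }

  all_groups <- config$groups
  rows <- list(dplyr::bind_cols(
    tibble::tibble(removed = "none", removed_so_far = "",
                   group_info_gain = NA_real_),
    run_cv(all_groups)
  ))
  if (scheme == "cumulative") {
    order_asc <- gig$group
    removed <- character(0)
    for (g in order_asc) {
      if (length(setdiff(all_groups, c(removed, g))) == 0L) break
      removed <- c(removed, g)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(removed = g,
                       removed_so_far = paste(removed, collapse = ","),
                       group_info_gain = gig$info_gain[gig$group == g]),
        run_cv(setdiff(all_groups, removed))
      )
    }
  } else {
    for (g in all_groups) {
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(removed = g, removed_so_far = g,
                       group_info_gain = gig$info_gain[gig$group == g]),
        run_cv(setdiff(all_groups, g))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "group_ig") <- gig
  attr(out, "scheme") <- scheme
  class(out) <- c("linker_ablation", class(out))
  out
}
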