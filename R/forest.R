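#' Train the per-residue random forest classifier
#'
#' Fits an ensemble of classification trees to per-residue feature vectors:
#' each tree is grown on a bootstrap sample of size N drawn with replacement;
#' at every node `m_features` candidate features are drawn uniformly without
#' replacement and the Gini-impurity-minimizing split among them is taken;
#' trees grow until the leaves are pure (no depth limit). Prediction is by
#' majority vote across trees. No class weighting or resampling is applied —
#' the classifier is trained on the raw, typically highly imbalanced,
#' residue labels. Training is deterministic given `seed`.
#'
#' The ensemble is fitted by \pkg{ranger}, configured to this exact recipe.
#'
#' @param x N x M feature matrix (or data frame); column names become the
#'   model's feature names.
#' @param y Length-N binary labels (0/1, logical, or a 2-level factor);
#'   1 = linker is the positive class.
#' @param n_trees Number of trees, default 200 (beyond which accuracy gains
#'   no longer justify the compute).
#' @param m_features Features tried at each node; `"auto"` (default) uses
#'   `floor(log2(M)) + 1` — 5 for the default 22-feature encoding.
#' @param seed Integer seed controlling bootstrap and feature subsampling.
#' @param vote_threshold Vote fraction at or above which a residue is called
#'   a linker (default 0.5; ties with an even ensemble go to linker).
#' @param min_linker_run Minimum length of a predicted linker run; shorter
#'   runs are relabelled domain (default 0 = raw per-residue output).
#' @param bootstrap Set `FALSE` to fit every tree on the full sample without
#'   resampling (used by the single-tree reduction oracle in the tests).
#' @return An object of class `linker_forest`.
#' @export
train_forest <- function(x, y, n_trees = 200, m_features = "auto", seed = 1L,
                         vote_threshold = 0.5, min_linker_run = 0L,
                         bootstrap = TRUE) {
  x <- as.data.frame(x)
  M <- ncol(x)
  if (M == 0L) stop("feature matrix has no columns", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 training instances", call. = FALSE)
  if (is.null(names(x)) || any(names(x) == "")) {
    names(x) <- paste0("f", seq_len(M))
  }
  if (identical(m_features, "auto")) {
    m_features <- floor(log2(M)) + 1L
  }
  m_features <- as.integer(m_features)
  if (m_features < 1L || m_features > M) {
    stop("m_features must be in 1..", M, call. = FALSE)
  }
  stopifnot(vote_threshold > 0, vote_threshold < 1, min_linker_run >= 0)

  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) y <- as.integer(y)
  if (is.character(y)) y <- suppressWarnings(as.integer(y))
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("y must be binary with 1 = linker", call. = FALSE)
  }
  yf <- factor(y, levels = c(0L, 1L))
  if (length(yf) != nrow(x)) stop("x and y lengths differ", call. = FALSE)

  # one-class training sets are a documented degenerate case; silence the
  # backend's dropped-level notice for them
  muffle_dropped_level <- function(w) {
    if (grepl("Dropped unused factor level", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  }
  fit <- withCallingHandlers(ranger::ranger(
    x = x, y = yf,
    num.trees = n_trees,
    mtry = m_features,
    replace = bootstrap,
    sample.fraction = 1,
    min.node.size = 1,
    splitrule = "gini",
    importance = "impurity",
    seed = seed,
    num.threads = 1
  ), warning = muffle_dropped_level)

  structure(
    list(
      fit = fit,
      feature_names = names(x),
      n_trees = n_trees,
      m_features = m_features,
      seed = seed,
      vote_threshold = vote_threshold,
      min_linker_run = as.integer(min_linker_run),
      bootstrap = bootstrap,
      class_priors = c(domain = mean(yf == "0"), linker = mean(yf == "1")),
      oob_error = fit$prediction.error
    ),
    class = "linker_forest"
  )
}

#' @export
print.linker_forest <- function(x, ...) {
  cat(sprintf(
    "<linker_forest> %d trees, m = %d of %d features, seed %d\n  training priors: %.1f%% linker; OOB error %.4f\n",
    x$n_trees, x$m_features, length(x$feature_names), x$seed,
    100 * x$class_priors[["linker"]], x$oob_error
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-feature Gini importance of a fitted forest
#'
#' @param x A `linker_forest`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `importance`, sorted descending.
#' @export
tidy.linker_forest <- function(x, ...) {
  imp <- ranger::importance(x$fit)
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-row summary of a fitted forest
#'
#' @param x A `linker_forest`.
#' @param ... Unused.
#' @return A one-row tibble with the hyperparameters and OOB error.
#' @export
glance.linker_forest <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees, m_features = x$m_features,
    n_features = length(x$feature_names),
    linker_prior = unname(x$class_priors[["linker"]]),
    oob_error = x$oob_error, seed = x$seed
  )
}

#' Predict per-residue linker votes for a profile
#'
#' Runs every tree of the forest on each residue's windowed feature vector
#' and reports the fraction of trees voting linker, the thresholded label
#' (vote fraction >= the model's `vote_threshold`; with the 0.5 default an
#' exactly split even ensemble calls linker), and — after suppressing runs
#' shorter than `min_linker_run` — the derived maximal linker segments.
#'
#' @param model A `linker_forest`.
#' @param profile A `residue_profile`, a numeric matrix with matching
#'   feature names, or a profiles tibble from [build_profiles()] (predicts
#'   every row).
#' @return An object of class `linker_prediction`: a tibble with columns
#'   `seq_id`, `pos`, `vote_fraction`, `label`, with the predicted segment
#'   table in attribute `"segments"`.
#' @export
predict_votes <- function(model, profile) {
  stopifnot(inherits(model, "linker_forest"))
  if (is.data.frame(profile) && "profile" %in% names(profile)) {
    preds <- purrr::map(profile$profile, function(p) predict_votes(model, p))
    out <- dplyr::bind_rows(preds)
    attr(out, "segments") <- dplyr::bind_rows(purrr::map(preds, attr, "segments"))
    class(out) <- c("linker_prediction", class(tibble::tibble()))
    return(out)
  }
  if (inherits(profile, "residue_profile")) {
    mat <- profile$matrix
    colnames(mat) <- profile$feature_names
    seq_id <- profile$seq_id
  } else {
    mat <- as.matrix(profile)
    seq_id <- NA_character_
  }
  if (!identical(colnames(mat), model$feature_names)) {
    stop("profile feature names do not match the model's training features",
         call. = FALSE)
  }
  pv <- stats::predict(model$fit, as.data.frame(mat), predict.all = TRUE,
                       num.threads = 1)$predictions
  # ranger stores class levels; per-tree votes come back as level indices
  linker_idx <- which(model$fit$forest$levels == "1")
  vote <- rowMeans(pv == linker_idx)
  lab <- as.integer(vote >= model$vote_threshold)
  lab <- filter_min_run(lab, model$min_linker_run)
  out <- tibble::tibble(
    seq_id = seq_id, pos = seq_len(nrow(mat)),
    vote_fraction = vote, label = lab
  )
  seg <- labels_to_segments(lab)
  attr(out, "segments") <- if (nrow(seg) > 0L) {
    tibble::tibble(seq_id = seq_id, start = seg$start, end = seg$end,
                   label = "linker")
  } else {
    tibble::tibble(seq_id = character(), start = integer(), end = integer(),
                   label = character())
  }
  class(out) <- c("linker_prediction", class(tibble::tibble()))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Suppress predicted linker runs shorter than a minimum length
#'
#' @param labels Binary integer vector.
#' @param min_run Minimum run length kept; 0 or 1 keeps everything.
#' @return The filtered label vector.
#' @export
filter_min_run <- function(labels, min_run) {
  if (min_run <= 1L) return(as.integer(labels))
  r <- rle(as.integer(labels))
  r$values[r$values == 1L & r$lengths < min_run] <- 0L
  inverse.rle(r)
}

#' Extract the predicted linker segments
#'
#' @param prediction A `linker_prediction`.
#' @return The segment tibble (`seq_id`, `start`, `end`, `label`).
#' @export
prediction_segments <- function(prediction) {
  attr(prediction, "segments")
}

#' Save / load a fitted forest
#'
#' The model (ranger ensemble, feature names, thresholds, seed) is written as
#' a single serialized file with a format-version marker.
#'
#' @param model A `linker_forest`.
#' @param path File path.
#' @return `path` (write) or the restored `linker_forest` (read).
#' @export
write_forest <- function(model, path) {
  stopifnot(inherits(model, "linker_forest"))
  saveRDS(list(format = "linkerforest_model_v1", model = model), path)
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "linkerforest_model_v1")) {
    stop("not a linkerforest model file: ", path, call. = FALSE)
  }
  obj$model
}
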