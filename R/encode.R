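#' Feature-encoding configuration
#'
#' Fixes how each residue is turned into a numeric feature vector before
#' window averaging. The vector is the concatenation, in this fixed order, of
#' the seven feature groups:
#' `linker_index | hydrophobicity | charge | polarity | aromaticity | size | electronic`.
#'
#' The hydrophobicity block is the SARAH1 signed five-bit code by default
#' (5 columns), or a single column for the kcal/mol (pH 7) or Rose scales.
#' Categorical properties are one-hot by default, so after window averaging
#' each block holds within-window category fractions; the ordinal option
#' collapses each property to a single integer-coded column.
#'
#' With the defaults the feature dimension is
#' `1 + 5 + 3 + 2 + 3 + 3 + 5 = 22`; with `hydrophobicity = "kcal_ph7"` it is
#' 18.
#'
#' @param hydrophobicity Hydrophobicity scale: `"sarah1"`, `"kcal_ph7"`, or
#'   `"rose"`.
#' @param categorical Encoding for the five categorical properties:
#'   `"one_hot"` or `"ordinal"`.
#' @param use_linker_index Include the linker-propensity index column?
#' @param linker_index_source Where the index values come from when building
#'   profiles inside [cross_validate()]: `"estimated_from_training"`
#'   (re-estimated on each training fold) or `"packaged"` (the shipped
#'   composition table everywhere).
#' @param groups Feature groups to include, a subset of
#'   `c("linker_index", "hydrophobicity", "charge", "polarity", "aromaticity",
#'   "size", "electronic")`. Defaults to all (minus `linker_index` when
#'   `use_linker_index` is `FALSE`). Used by the ablation machinery.
#' @return An object of class `encoding_config`.
#' @examples
#' cfg <- encoding_config()
#' length(feature_names(cfg))
#' @export
encoding_config <- function(hydrophobicity = c("sarah1", "kcal_ph7", "rose"),
                            categorical = c("one_hot", "ordinal"),
                            use_linker_index = TRUE,
                            linker_index_source = c("estimated_from_training", "packaged"),
                            groups = NULL) {
  hydrophobicity <- match.arg(hydrophobicity)
  categorical <- match.arg(categorical)
  linker_index_source <- match.arg(linker_index_source)
  all_groups <- feature_group_names()
  if (is.null(groups)) {
    groups <- all_groups
    if (!use_linker_index) groups <- setdiff(groups, "linker_index")
  } else {
    if (!all(groups %in% all_groups)) {
      stop("unknown feature group(s): ",
           paste(setdiff(groups, all_groups), collapse = ", "), call. = FALSE)
    }
    groups <- all_groups[all_groups %in% groups]
    if (!use_linker_index) groups <- setdiff(groups, "linker_index")
  }
  if (length(groups) == 0L) stop("encoding must keep at least one feature group", call. = FALSE)
  structure(
    list(hydrophobicity = hydrophobicity, categorical = categorical,
         use_linker_index = use_linker_index,
         linker_index_source = linker_index_source, groups = groups),
    class = "encoding_config"
  )
}

#' @export
print.encoding_config <- function(x, ...) {
  cat("<encoding_config>",
      sprintf("hydrophobicity=%s, categorical=%s, index=%s (%s)",
              x$hydrophobicity, x$categorical,
              if ("linker_index" %in% x$groups) "yes" else "no",
              x$linker_index_source),
      sprintf("\n  groups: %s", paste(x$groups, collapse = ", ")),
      sprintf("\n  D = %d\n", length(feature_names(x))))
  invisible(x)
}

#' The seven feature-group names, in encoding order
#' @return Character vector of group names.
#' @export
feature_group_names <- function() {
  c("linker_index", "hydrophobicity", "charge", "polarity",
    "aromaticity", "size", "electronic")
}

#' Feature names of an encoding configuration
#'
#' @param config An [encoding_config()].
#' @return Character vector of the D column names, stable for a fixed config.
#' @export
feature_names <- function(config) {
  names(feature_group_map(config))
}

#' Map profile columns to their feature group
#'
#' @param config An [encoding_config()].
#' @return A named character vector: names are feature (column) names, values
#'   the owning group.
#' @export
feature_group_map <- function(config) {
  stopifnot(inherits(config, "encoding_config"))
  out <- character(0)
  add <- function(map, nms, group) c(map, stats::setNames(rep(group, length(nms)), nms))
  for (g in config$groups) {
    out <- switch(g,
      linker_index = add(out, "linker_index", g),
      hydrophobicity = add(out, switch(config$hydrophobicity,
        sarah1 = paste0("sarah1_b", 1:5),
        kcal_ph7 = "hydro_kcal_ph7",
        rose = "hydro_rose"), g),
      # categorical groups
      {
        lev <- .aa_category_levels[[g]]
        if (config$categorical == "one_hot") {
          add(out, paste0(g, "_", lev), g)
        } else {
          add(out, g, g)
        }
      }
    )
  }
  out
}

# 20 x D lookup matrix: row per standard amino acid, columns = feature_names
encoding_lut <- function(tables, config) {
  stopifnot(inherits(tables, "aa_property_tables"),
            inherits(config, "encoding_config"))
  blocks <- list()
  for (g in config$groups) {
    blocks[[g]] <- switch(g,
      linker_index = {
        idx <- stats::setNames(tables$composition$linker_index, tables$composition$aa)
        matrix(idx[AA_STANDARD], ncol = 1, dimnames = list(AA_STANDARD, "linker_index"))
      },
      hydrophobicity = switch(config$hydrophobicity,
        sarah1 = {
          m <- tables$sarah1[AA_STANDARD, , drop = FALSE]
          colnames(m) <- paste0("sarah1_b", 1:5)
          m
        },
        kcal_ph7 = matrix(tables$hydro_kcal[AA_STANDARD], ncol = 1,
                          dimnames = list(AA_STANDARD, "hydro_kcal_ph7")),
        rose = matrix(tables$hydro_rose[AA_STANDARD], ncol = 1,
                      dimnames = list(AA_STANDARD, "hydro_rose"))
      ),
      {
        lev <- .aa_category_levels[[g]]
        vals <- stats::setNames(tables$categories[[g]], tables$categories$aa)[AA_STANDARD]
        if (config$categorical == "one_hot") {
          m <- matrix(0, nrow = 20, ncol = length(lev),
                      dimnames = list(AA_STANDARD, paste0(g, "_", lev)))
          m[cbind(seq_len(20), match(vals, lev))] <- 1
          m
        } else {
          matrix(match(vals, lev), ncol = 1, dimnames = list(AA_STANDARD, g))
        }
      }
    )
  }
  do.call(cbind, unname(blocks))
}

#' Encode the residues of one sequence as raw (unwindowed) features
#'
#' Each residue is mapped to its D-dimensional feature vector; rows in
#' sequence order. One-hot categorical blocks contain exactly one 1 per row.
#'
#' @param residues A single sequence string over the standard alphabet.
#' @param tables [aa_property_tables()].
#' @param config [encoding_config()].
#' @return An L x D numeric matrix with feature names as column names.
#' @export
encode_residues <- function(residues, tables, config = encoding_config()) {
  stopifnot(is.character(residues), length(residues) == 1L)
  chars <- strsplit(residues, "")[[1]]
  bad <- !(chars %in% AA_STANDARD)
  if (any(bad)) {
    stop("non-standard residue(s) in sequence: ",
         paste(unique(chars[bad]), collapse = ", "),
         " (sanitize upstream with read_fasta)", call. = FALSE)
  }
  lut <- encoding_lut(tables, config)
  m <- lut[chars, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Sliding-window average of a feature matrix
#'
#' Replaces each row j of the L x D matrix by the mean of the rows in the
#' window of size `w` centred on j, clipped at both termini: positions
#' `max(1, j - (w-1)/2) .. min(L, j + (w-1)/2)`, with the denominator equal
#' to the number of positions actually included. `w = 1` is the identity; a
#' window larger than the sequence averages the whole sequence at every
#' position.
#'
#' @param raw An L x D numeric matrix (or a numeric vector, treated as L x 1).
#' @param w Odd positive window size.
#' @return A matrix of the same shape (a vector input returns a vector).
#' @examples
#' window_average(c(1, 2, 3, 4, 5), 3) # 1.5 2 3 4 4.5
#' @export
window_average <- function(raw, w) {
  if (length(w) != 1L || !is.finite(w) || w < 1 || w != as.integer(w) || w %% 2 == 0) {
    stop("window size must be an odd positive integer", call. = FALSE)
  }
  vec_in <- is.null(dim(raw))
  if (vec_in) raw <- matrix(as.numeric(raw), ncol = 1)
  L <- nrow(raw)
  stopifnot(L >= 1L)
  if (w == 1) return(if (vec_in) raw[, 1] else raw)
  h <- (w - 1) / 2
  cs <- rbind(0, apply(raw, 2, cumsum))
  j <- seq_len(L)
  lo <- pmax(1, j - h)
  hi <- pmin(L, j + h)
  out <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  dimnames(out) <- dimnames(raw)
  rownames(out) <- NULL
  if (vec_in) out[, 1] else out
}

#' Build the windowed feature profile of one sequence
#'
#' Encodes every residue ([encode_residues()]) and averages the encoding over
#' a sliding window ([window_average()]). Every profile row is a convex
#' combination of raw encoding rows, so windowed one-hot blocks are
#' within-window category fractions summing to 1.
#'
#' @param residues A single sequence string.
#' @param tables [aa_property_tables()].
#' @param config [encoding_config()].
#' @param window Odd window size; default 41 (the size at which recall,
#'   precision and F-measure peak in the window sweep).
#' @param seq_id Optional identifier stored in the result.
#' @return An object of class `residue_profile`: list with `seq_id`,
#'   `matrix` (L x D), `feature_names`, `window`.
#' @export
build_profile <- function(residues, tables, config = encoding_config(),
                          window = 41, seq_id = NA_character_) {
  raw <- encode_residues(residues, tables, config)
  structure(
    list(seq_id = seq_id, matrix = window_average(raw, window),
         feature_names = colnames(raw), window = window),
    class = "residue_profile"
  )
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("<residue_profile> %s: %d residues x %d features, window %d\n",
              x$seq_id, nrow(x$matrix), ncol(x$matrix), x$window))
  invisible(x)
}

#' Build windowed profiles for every sequence of a corpus
#'
#' @param corpus A tibble with columns `seq_id`, `residues`.
#' @param tables [aa_property_tables()].
#' @param config [encoding_config()].
#' @param window Odd window size, default 41.
#' @return The corpus tibble with an added `profile` list-column of
#'   `residue_profile` objects.
#' @export
build_profiles <- function(corpus, tables, config = encoding_config(), window = 41) {
  out <- tibble::as_tibble(corpus)
  out$profile <- purrr::map2(
    corpus$residues, corpus$seq_id,
    function(r, id) build_profile(r, tables, config, window, seq_id = id)
  )
  out
}
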