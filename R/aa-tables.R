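#' The twenty standard amino acids
#'
#' One-letter codes of the twenty standard amino acids, in alphabetical order.
#' All property tables, encodings, and the synthetic generator are restricted
#' to this alphabet; non-standard residues (X, B, Z, U, O) are handled at the
#' I/O boundary by [read_fasta()]'s sanitize policy.
#'
#' @format A character vector of length 20.
#' @export
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# category levels, in the fixed order used by one-hot blocks and ordinal codes
.aa_category_levels <- list(
  charge      = c("positive", "negative", "neutral"),
  polarity    = c("polar", "nonpolar"),
  aromaticity = c("aliphatic", "aromatic", "neutral"),
  size        = c("small", "medium", "large"),
  electronic  = c("strong_donor", "weak_donor", "neutral",
                  "weak_acceptor", "strong_acceptor")
)

.read_aa_tsv <- function(name) {
  path <- system.file("extdata", name, package = "linkerforest", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Amino-acid property tables
#'
#' Loads the packaged per-residue property tables used to encode protein
#' sequences: linker/domain amino-acid compositions with the derived
#' linker-propensity index, three hydrophobicity scales (SARAH1 signed
#' five-bit code, kcal/mol at pH 7, Rose buried-area scale), and the five
#' categorical physiochemical classifications (side-chain charge, polarity,
#' aromaticity, size, electronic character).
#'
#' The packaged composition table can be replaced by an estimate from a
#' training corpus (see [compute_linker_index()]); the replacement must carry
#' the same columns (`aa`, `linker_pct`, `domain_pct`, `linker_index`) and
#' cover all twenty standard amino acids.
#'
#' @param composition Optional replacement for the packaged composition /
#'   linker-index tibble, e.g. the output of [compute_linker_index()].
#' @return An object of class `aa_property_tables`: a list with elements
#'   `composition` (tibble: `aa`, `linker_pct`, `domain_pct`, `linker_index`),
#'   `hydro_kcal` and `hydro_rose` (named numeric vectors), `sarah1`
#'   (20 x 5 numeric matrix, rows named by residue), and `categories`
#'   (tibble: `aa` plus one column per categorical property).
#' @examples
#' tabs <- aa_property_tables()
#' tabs$composition
#' @export
aa_property_tables <- function(composition = NULL) {
  comp <- if (is.null(composition)) .read_aa_tsv("aa_linker_composition.tsv") else composition
  kcal <- .read_aa_tsv("hydrophobicity_kcal_ph7.tsv")
  rose <- .read_aa_tsv("hydrophobicity_rose.tsv")
  sarah <- .read_aa_tsv("sarah1.tsv")
  cats <- .read_aa_tsv("aa_categories.tsv")

  sarah_m <- as.matrix(sarah[, c("b1", "b2", "b3", "b4", "b5")])
  rownames(sarah_m) <- sarah$aa

  out <- structure(
    list(
      composition = tibble::as_tibble(comp),
      hydro_kcal = stats::setNames(kcal$value, kcal$aa),
      hydro_rose = stats::setNames(rose$value, rose$aa),
      sarah1 = sarah_m,
      categories = tibble::as_tibble(cats)
    ),
    class = "aa_property_tables"
  )
  validate_property_tables(out)
  out
}

#' Validate a set of amino-acid property tables
#'
#' Checks the structural invariants every table set must satisfy: each table
#' covers exactly the twenty standard amino acids; every SARAH1 code has
#' exactly two non-zero entries; each categorical property assigns exactly one
#' level to every residue; and the composition table's `linker_index` column
#' agrees with `-ln(linker_pct / domain_pct)` within `index_tol`.
#'
#' @param tables An `aa_property_tables` object.
#' @param index_tol Permitted absolute disagreement between the stored index
#'   and the index recomputed from the stored frequencies. The default 0.005
#'   absorbs two-decimal rounding of the frequency columns.
#' @return `tables`, invisibly. Errors on any violated invariant.
#' @export
validate_property_tables <- function(tables, index_tol = 0.005) {
  stopifnot(inherits(tables, "aa_property_tables"))
  comp <- tables$composition

  check_cover <- function(aas, what) {
    if (!setequal(aas, AA_STANDARD) || anyDuplicated(aas) > 0) {
      stop(what, " must cover exactly the 20 standard amino acids", call. = FALSE)
    }
  }
  check_cover(comp$aa, "composition table")
  check_cover(names(tables$hydro_kcal), "kcal/mol hydrophobicity table")
  check_cover(names(tables$hydro_rose), "Rose hydrophobicity table")
  check_cover(rownames(tables$sarah1), "SARAH1 table")
  check_cover(tables$categories$aa, "category table")

  if (!all(rowSums(tables$sarah1 != 0) == 2)) {
    stop("every SARAH1 code must have exactly two non-zero entries", call. = FALSE)
  }
  if (!all(tables$sarah1 %in% c(-1, 0, 1))) {
    stop("SARAH1 entries must be in {-1, 0, 1}", call. = FALSE)
  }

  for (prop in names(.aa_category_levels)) {
    vals <- tables$categories[[prop]]
    if (is.null(vals) || anyNA(vals) || !all(vals %in% .aa_category_levels[[prop]])) {
      stop("category table column '", prop, "' must assign one of {",
           paste(.aa_category_levels[[prop]], collapse = ", "),
           "} to every amino acid", call. = FALSE)
    }
  }

  pc <- attr(comp, "pseudocount") %||% 0
  recomputed <- -log((comp$linker_pct + pc) / (comp$domain_pct + pc))
  dev <- abs(recomputed - comp$linker_index)
  if (any(dev > index_tol)) {
    bad <- comp$aa[which.max(dev)]
    stop(sprintf(
      "stored linker_index disagrees with -ln(linker_pct/domain_pct) by %.4f (residue %s), tolerance %.4f",
      max(dev), bad, index_tol
    ), call. = FALSE)
  }
  invisible(tables)
}

#' @export
print.aa_property_tables <- function(x, ...) {
  cat("<aa_property_tables>\n")
  cat("  composition + linker index: 20 residues\n")
  cat("  hydrophobicity scales: sarah1 (5-bit signed), kcal_ph7, rose\n")
  cat("  categorical properties:", paste(names(.aa_category_levels), collapse = ", "), "\n")
  invisible(x)
}

#' Estimate the linker-propensity index from an annotated corpus
#'
#' Computes, for every standard amino acid, its percentage frequency among
#' linker-labelled residues and among domain-labelled residues, and the
#' propensity index
#' \deqn{S_i = -\ln\frac{f_i^{linker} + c}{f_i^{domain} + c}}
#' where \eqn{c} is an optional pseudocount added to both percentages.
#' Negative \eqn{S_i} marks residues over-represented in linkers.
#'
#' A residue absent from both partitions gets index 0 with a warning (no
#' evidence either way). A residue absent from exactly one partition with
#' `pseudocount = 0` would give an infinite index; this errors with a message
#' suggesting a positive pseudocount.
#'
#' @param corpus An annotated corpus: a data frame with columns `residues`
#'   (character) and `labels` (list of integer vectors, 1 = linker residue),
#'   as returned by [read_annotations()] or [generate_corpus()].
#' @param pseudocount Non-negative value added to both percentage frequencies
#'   before taking the log ratio. Default 0.
#' @return A tibble with columns `aa`, `linker_pct`, `domain_pct`,
#'   `linker_index`, ordered by ascending index (strongest linker preference
#'   first). Each percentage column sums to 100 over the residues present.
#' @examples
#' corp <- generate_corpus(20, seed = 1)
#' compute_linker_index(corp)
#' @export
compute_linker_index <- function(corpus, pseudocount = 0) {
  stopifnot(is.data.frame(corpus), pseudocount >= 0)
  res <- strsplit(paste(corpus$residues, collapse = ""), "")[[1]]
  lab <- unlist(corpus$labels, use.names = FALSE)
  if (length(res) != length(lab)) {
    stop("label vectors do not match sequence lengths", call. = FALSE)
  }
  n_link <- sum(lab == 1L)
  n_dom <- sum(lab == 0L)
  if (n_link == 0L || n_dom == 0L) {
    stop("corpus must contain at least one linker and one domain residue", call. = FALSE)
  }
  cnt_l <- table(factor(res[lab == 1L], levels = AA_STANDARD))
  cnt_d <- table(factor(res[lab == 0L], levels = AA_STANDARD))
  f_l <- 100 * as.numeric(cnt_l) / n_link
  f_d <- 100 * as.numeric(cnt_d) / n_dom

  absent_both <- f_l == 0 & f_d == 0
  if (any(absent_both)) {
    warning("amino acid(s) absent from both partitions, index set to 0: ",
            paste(AA_STANDARD[absent_both], collapse = ", "), call. = FALSE)
  }
  one_sided <- xor(f_l == 0, f_d == 0)
  if (pseudocount == 0 && any(one_sided)) {
    stop("amino acid(s) observed in only one partition (",
         paste(AA_STANDARD[one_sided], collapse = ", "),
         "); use a positive pseudocount to avoid an infinite index", call. = FALSE)
  }

  s <- -log((f_l + pseudocount) / (f_d + pseudocount))
  s[absent_both] <- 0

  out <- tibble::tibble(
    aa = AA_STANDARD,
    linker_pct = f_l,
    domain_pct = f_d,
    linker_index = s
  ) |>
    dplyr::arrange(.data$linker_index)
  attr(out, "pseudocount") <- pseudocount
  out
}
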