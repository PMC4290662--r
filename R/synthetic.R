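#' Sample rounded, truncated Gamma segment lengths
#'
#' Lengths are drawn from a Gamma distribution with the given mean and shape,
#' rounded to integers, and truncated by rejection to `[lo, hi]`. The Gamma
#' family is used because segment lengths are positive and right-skewed and
#' the available calibration is a mean plus hard bounds.
#'
#' @param n Number of lengths.
#' @param mean Mean of the untruncated Gamma law.
#' @param shape Gamma shape parameter (default 4).
#' @param lo,hi Inclusive truncation bounds.
#' @return Integer vector of length `n`.
#' @keywords internal
rtrunc_gamma_len <- function(n, mean, shape = 4, lo, hi) {
  stopifnot(mean > 0, shape > 0, lo <= hi)
  rate <- shape / mean
  mass <- stats::pgamma(hi + 0.5, shape, rate) - stats::pgamma(lo - 0.5, shape, rate)
  if (mass < 1e-8) {
    stop(sprintf("length law (mean %.1f) has essentially no mass in [%d, %d]",
                 mean, lo, hi), call. = FALSE)
  }
  out <- integer(0)
  while (length(out) < n) {
    draw <- as.integer(round(stats::rgamma(max(n, 16L), shape, rate)))
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Amplify the divergence between two compositions
#'
#' Scales the log-ratio of the linker and domain compositions about their
#' per-residue geometric mean by `multiplier`, then renormalizes each to
#' 100%. `multiplier = 1` returns the inputs (renormalized); larger values
#' give a single effect-size knob for separability and power-style tests.
#'
#' @param linker,domain Named numeric vectors (percent per amino acid).
#' @param multiplier Real >= 1.
#' @return A list with elements `linker` and `domain` (named, sum 100).
#' @export
diverge_compositions <- function(linker, domain, multiplier = 1) {
  stopifnot(multiplier >= 1, setequal(names(linker), names(domain)))
  domain <- domain[names(linker)]
  g <- sqrt(linker * domain)
  r <- log(linker / domain)
  l2 <- g * exp(multiplier * r / 2)
  d2 <- g * exp(-multiplier * r / 2)
  list(linker = 100 * l2 / sum(l2), domain = 100 * d2 / sum(d2))
}

.default_composition <- function(which = c("linker", "domain")) {
  which <- match.arg(which)
  comp <- .read_aa_tsv("aa_linker_composition.tsv")
  col <- if (which == "linker") comp$linker_pct else comp$domain_pct
  stats::setNames(col, comp$aa)
}

.check_composition <- function(x, what) {
  if (!setequal(names(x), AA_STANDARD)) {
    stop(what, " composition must name exactly the 20 standard amino acids",
         call. = FALSE)
  }
  if (abs(sum(x) - 100) > 0.1) {
    stop(what, " composition must sum to 100% (within 0.1)", call. = FALSE)
  }
  100 * x[AA_STANDARD] / sum(x)
}

#' Generate an annotated synthetic multi-domain corpus
#'
#' Each sequence is an alternating domain-linker-domain-...-domain structure
#' that starts and ends with a domain. Residues are drawn i.i.d. from the
#' partition's amino-acid composition (linker and domain compositions default
#' to the packaged linker/domain frequency columns); segment lengths are drawn
#' from rounded Gamma laws truncated to the canonical ranges (domains 25-500
#' residues, mean 147.1; linkers 10-100 residues, mean 12.7). The whole corpus
#' is reproducible from `seed`.
#'
#' The i.i.d. within-partition sampling is exactly the structure the
#' linker-propensity index (a zeroth-order composition statistic) assumes; no
#' higher-order sequence correlation is simulated.
#'
#' @param n_sequences Number of sequences.
#' @param domains_per_sequence Integer vector of allowed domain counts, drawn
#'   uniformly per sequence. Default `2:3`.
#' @param domain_length_mean,domain_length_shape,domain_length_range
#'   Parameters of the domain length law.
#' @param linker_length_mean,linker_length_shape,linker_length_range
#'   Parameters of the linker length law.
#' @param linker_composition,domain_composition Named percent vectors over the
#'   20 standard amino acids; default packaged columns.
#' @param divergence_multiplier Real >= 1; amplifies the compositional
#'   difference between the two partitions via [diverge_compositions()].
#' @param seed Integer seed; the generator uses its own RNG stream and does
#'   not disturb the caller's.
#' @return An annotated corpus tibble (`seq_id`, `residues`, `labels`), with
#'   the truth segment table in attribute `"segments"` and the resolved
#'   configuration in attribute `"config"`.
#' @examples
#' corp <- generate_corpus(3, seed = 7)
#' corpus_stats(corp)
#' @export
generate_corpus <- function(n_sequences,
                            domains_per_sequence = 2:3,
                            domain_length_mean = 147.1,
                            domain_length_shape = 4,
                            domain_length_range = c(25L, 500L),
                            linker_length_mean = 12.7,
                            linker_length_shape = 4,
                            linker_length_range = c(10L, 100L),
                            linker_composition = NULL,
                            domain_composition = NULL,
                            divergence_multiplier = 1,
                            seed = 1L) {
  stopifnot(n_sequences >= 1, all(domains_per_sequence >= 2))
  if (is.null(linker_composition)) linker_composition <- .default_composition("linker")
  if (is.null(domain_composition)) domain_composition <- .default_composition("domain")
  linker_composition <- .check_composition(linker_composition, "linker")
  domain_composition <- .check_composition(domain_composition, "domain")
  comps <- diverge_compositions(linker_composition, domain_composition,
                                divergence_multiplier)

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  seq_ids <- sprintf("syn%05d", seq_len(n_sequences))
  residues <- character(n_sequences)
  labels <- vector("list", n_sequences)
  seg_rows <- vector("list", n_sequences)

  for (i in seq_len(n_sequences)) {
    nd <- if (length(domains_per_sequence) == 1L) domains_per_sequence else
      sample(domains_per_sequence, 1L)
    dl <- rtrunc_gamma_len(nd, domain_length_mean, domain_length_shape,
                           domain_length_range[1], domain_length_range[2])
    ll <- rtrunc_gamma_len(nd - 1L, linker_length_mean, linker_length_shape,
                           linker_length_range[1], linker_length_range[2])
    # interleave: D1 L1 D2 L2 ... D_nd
    lens <- integer(2L * nd - 1L)
    lens[seq(1L, 2L * nd - 1L, by = 2L)] <- dl
    if (nd > 1L) lens[seq(2L, 2L * nd - 2L, by = 2L)] <- ll
    is_linker <- rep(c(FALSE, TRUE), length.out = 2L * nd - 1L)
    chars <- character(sum(lens))
    lab <- integer(sum(lens))
    pos <- 0L
    starts <- integer(0); ends <- integer(0)
    for (s in seq_along(lens)) {
      comp <- if (is_linker[s]) comps$linker else comps$domain
      idx <- (pos + 1L):(pos + lens[s])
      chars[idx] <- sample(AA_STANDARD, lens[s], replace = TRUE, prob = comp)
      if (is_linker[s]) {
        lab[idx] <- 1L
        starts <- c(starts, pos + 1L)
        ends <- c(ends, pos + lens[s])
      }
      pos <- pos + lens[s]
    }
    residues[i] <- paste(chars, collapse = "")
    labels[[i]] <- lab
    seg_rows[[i]] <- if (length(starts) > 0L) {
      tibble::tibble(seq_id = seq_ids[i], start = starts, end = ends,
                     label = "linker")
    }
  }

  out <- tibble::tibble(seq_id = seq_ids, residues = residues, labels = labels)
  attr(out, "segments") <- dplyr::bind_rows(seg_rows)
  attr(out, "config") <- list(
    n_sequences = n_sequences, domains_per_sequence = domains_per_sequence,
    domain_length_mean = domain_length_mean, domain_length_shape = domain_length_shape,
    domain_length_range = domain_length_range,
    linker_length_mean = linker_length_mean, linker_length_shape = linker_length_shape,
    linker_length_range = linker_length_range,
    linker_composition = comps$linker, domain_composition = comps$domain,
    divergence_multiplier = divergence_multiplier, seed = seed
  )
  class(out) <- c("linker_corpus", class(tibble::tibble()))
  out
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Summary statistics of an annotated corpus
#'
#' Counts maximal domain and linker runs as segments and reports segment
#' counts, mean segment lengths, and the percentage of residues in each
#' partition.
#'
#' @param corpus An annotated corpus (tibble with `seq_id`, `residues`,
#'   `labels`).
#' @return A one-row tibble: `n_sequences`, `n_domain_segments`,
#'   `n_linker_segments`, `mean_domain_length`, `mean_linker_length`,
#'   `domain_residue_share`, `linker_residue_share` (percent, summing to 100).
#' @export
corpus_stats <- function(corpus) {
  if (nrow(corpus) == 0L) {
    return(tibble::tibble(
      n_sequences = 0L, n_domain_segments = 0L, n_linker_segments = 0L,
      mean_domain_length = NA_real_, mean_linker_length = NA_real_,
      domain_residue_share = NA_real_, linker_residue_share = NA_real_
    ))
  }
  dom_lens <- integer(0); link_lens <- integer(0)
  for (lab in corpus$labels) {
    r <- rle(as.integer(lab))
    dom_lens <- c(dom_lens, r$lengths[r$values == 0L])
    link_lens <- c(link_lens, r$lengths[r$values == 1L])
  }
  n_dom_res <- sum(dom_lens); n_link_res <- sum(link_lens)
  tot <- n_dom_res + n_link_res
  tibble::tibble(
    n_sequences = nrow(corpus),
    n_domain_segments = length(dom_lens),
    n_linker_segments = length(link_lens),
    mean_domain_length = if (length(dom_lens)) mean(dom_lens) else NA_real_,
    mean_linker_length = if (length(link_lens)) mean(link_lens) else NA_real_,
    domain_residue_share = 100 * n_dom_res / tot,
    linker_residue_share = 100 * n_link_res / tot
  )
}

#' Per-partition amino-acid compositions of a corpus
#'
#' @param corpus An annotated corpus.
#' @return A tibble with columns `aa`, `linker_pct`, `domain_pct` (each
#'   column sums to 100 over the residues present in that partition).
#' @export
corpus_compositions <- function(corpus) {
  res <- strsplit(paste(corpus$residues, collapse = ""), "")[[1]]
  lab <- unlist(corpus$labels, use.names = FALSE)
  cnt_l <- table(factor(res[lab == 1L], levels = AA_STANDARD))
  cnt_d <- table(factor(res[lab == 0L], levels = AA_STANDARD))
  tibble::tibble(
    aa = AA_STANDARD,
    linker_pct = 100 * as.numeric(cnt_l) / max(sum(cnt_l), 1),
    domain_pct = 100 * as.numeric(cnt_d) / max(sum(cnt_d), 1)
  )
}

#' Residue-share arithmetic from segment counts and mean lengths
#'
#' Given the number of domain and linker segments and their mean lengths,
#' returns the percentage of residues falling in each partition — the
#' standard back-of-envelope statistic for how imbalanced a linker dataset
#' is.
#'
#' @param n_domains,n_linkers Segment counts.
#' @param mean_domain_length,mean_linker_length Mean segment lengths.
#' @return A one-row tibble with `domain_residue_share` and
#'   `linker_residue_share` (percent).
#' @examples
#' segment_residue_shares(334, 147.1, 183, 12.7) # ~95.5% / 4.5%
#' @export
segment_residue_shares <- function(n_domains, mean_domain_length,
                                   n_linkers, mean_linker_length) {
  dom <- n_domains * mean_domain_length
  link <- n_linkers * mean_linker_length
  tibble::tibble(
    domain_residue_share = 100 * dom / (dom + link),
    linker_residue_share = 100 * link / (dom + link)
  )
}
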