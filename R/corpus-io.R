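#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a tibble of upper-case
#' sequences over the 20-letter amino-acid alphabet. Record identifiers are
#' the first whitespace-delimited token of each header line.
#'
#' Characters outside the standard alphabet (e.g. X, B, Z, U, O) are handled
#' by `sanitize`: `"drop"` (default) removes them with a warning, since the
#' property tables cover only the twenty standard residues; `"error"` aborts.
#'
#' @param path Path to a FASTA file.
#' @param sanitize Policy for non-standard residues: `"drop"` or `"error"`.
#' @return A tibble with columns `seq_id` (character) and `residues`
#'   (character, upper-case, standard alphabet only).
#' @export
read_fasta <- function(path, sanitize = c("drop", "error")) {
  sanitize <- match.arg(sanitize)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records found in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("\\s", "", seqs)
  seqs <- sanitize_residues(seqs, ids, sanitize)
  tibble::tibble(seq_id = ids, residues = unname(seqs))
}

sanitize_residues <- function(seqs, ids, policy) {
  bad_pat <- sprintf("[^%s]", paste(AA_STANDARD, collapse = ""))
  has_bad <- grepl(bad_pat, seqs)
  if (any(has_bad)) {
    if (policy == "error") {
      stop("non-standard residues in sequence(s): ",
           paste(ids[has_bad], collapse = ", "), call. = FALSE)
    }
    warning("dropped non-standard residues from sequence(s): ",
            paste(ids[has_bad], collapse = ", "), call. = FALSE)
    seqs[has_bad] <- gsub(bad_pat, "", seqs[has_bad])
  }
  if (any(nchar(seqs) == 0L)) {
    stop("sequence(s) empty after sanitization: ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Write a corpus to FASTA
#'
#' @param corpus A data frame with columns `seq_id` and `residues`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(corpus, path) {
  set <- Biostrings::AAStringSet(stats::setNames(corpus$residues, corpus$seq_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read segment annotations and derive per-residue labels
#'
#' Reads a tab-separated annotation file (columns `seq_id`, `start`, `end`,
#' `label`, 1-based inclusive coordinates, `#` comment lines allowed) and
#' attaches per-residue binary labels to the given sequences: residues covered
#' by a `linker` interval are labelled 1, all other residues 0. Annotation
#' files typically list linker segments only; explicit `domain` rows are
#' accepted and validated for bounds but do not change the default-domain
#' rule.
#'
#' If the file contains a `#SEGMENTS` marker line (as written by
#' [write_predictions()]), only the lines after the marker are parsed, so a
#' prediction file round-trips directly.
#'
#' @param path Path to the annotation TSV.
#' @param sequences A tibble of sequences as returned by [read_fasta()].
#' @return An annotated corpus: the `sequences` tibble with an added `labels`
#'   list-column of integer vectors, with the parsed segment table in
#'   attribute `"segments"`.
#' @export
read_annotations <- function(path, sequences) {
  lines <- readLines(path)
  marker <- which(lines == "#SEGMENTS")
  if (length(marker) > 0L) lines <- lines[(marker[length(marker)] + 1L):length(lines)]
  seg <- readr::read_tsv(I(paste(lines, collapse = "\n")),
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      seq_id = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      label = readr::col_character()
    )
  )
  annotate_corpus(sequences, seg)
}

#' Attach per-residue labels to sequences from a segment table
#'
#' The programmatic core of [read_annotations()]: validates the segment table
#' against the sequences and converts linker intervals into per-residue binary
#' labels (1 = linker).
#'
#' @param sequences A tibble with columns `seq_id`, `residues`.
#' @param segments A data frame with columns `seq_id`, `start`, `end`,
#'   `label` (`"linker"` or `"domain"`), coordinates 1-based inclusive.
#' @return An annotated corpus tibble (`seq_id`, `residues`, `labels`
#'   list-column), with `segments` stored in attribute `"segments"`.
#' @export
annotate_corpus <- function(sequences, segments) {
  stopifnot(all(c("seq_id", "residues") %in% names(sequences)))
  stopifnot(all(c("seq_id", "start", "end", "label") %in% names(segments)))
  if (!all(segments$label %in% c("linker", "domain"))) {
    stop("segment label must be 'linker' or 'domain'", call. = FALSE)
  }
  unknown <- setdiff(segments$seq_id, sequences$seq_id)
  if (length(unknown) > 0L) {
    stop("annotation refers to unknown sequence(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  lens <- stats::setNames(nchar(sequences$residues), sequences$seq_id)
  bad <- segments$start < 1L | segments$end < segments$start |
    segments$end > lens[segments$seq_id]
  if (any(bad)) {
    stop("out-of-bounds or inverted interval(s) for sequence(s): ",
         paste(unique(segments$seq_id[bad]), collapse = ", "), call. = FALSE)
  }

  labels <- vector("list", nrow(sequences))
  for (i in seq_len(nrow(sequences))) {
    L <- unname(lens[[i]])
    lab <- integer(L)
    rows <- segments[segments$seq_id == sequences$seq_id[i] &
                       segments$label == "linker", , drop = FALSE]
    if (nrow(rows) > 0L) {
      covered <- integer(L)
      for (r in seq_len(nrow(rows))) {
        idx <- rows$start[r]:rows$end[r]
        covered[idx] <- covered[idx] + 1L
      }
      if (any(covered > 1L)) {
        stop("overlapping linker intervals for sequence ",
             sequences$seq_id[i], call. = FALSE)
      }
      lab[covered == 1L] <- 1L
    }
    labels[[i]] <- lab
  }
  out <- tibble::as_tibble(sequences)
  out$labels <- labels
  attr(out, "segments") <- tibble::as_tibble(segments)
  class(out) <- c("linker_corpus", class(tibble::tibble()))
  out
}

#' @export
print.linker_corpus <- function(x, ...) {
  n_link <- sum(unlist(x$labels, use.names = FALSE))
  n_tot <- sum(lengths(x$labels))
  cat(sprintf("<linker_corpus> %d sequence(s), %d residues (%.1f%% linker)\n",
              nrow(x), n_tot, 100 * n_link / max(n_tot, 1)))
  NextMethod()
}

#' Convert a binary label vector to maximal linker runs
#'
#' @param labels Integer/logical vector; 1 (TRUE) marks linker residues.
#' @return A tibble with columns `start`, `end` (1-based inclusive), one row
#'   per maximal run of 1s.
#' @export
labels_to_segments <- function(labels) {
  labels <- as.integer(labels)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' Convert linker segments to a binary label vector
#'
#' @param segments A data frame with columns `start`, `end` (1-based inclusive).
#' @param len Sequence length.
#' @return Integer vector of length `len` with 1 inside the segments.
#' @export
segments_to_labels <- function(segments, len) {
  lab <- integer(len)
  for (r in seq_len(nrow(segments))) lab[segments$start[r]:segments$end[r]] <- 1L
  lab
}

#' Extract the linker segment table of an annotated corpus
#'
#' Derives maximal linker runs from the per-residue labels (not from the
#' `"segments"` attribute, so it also applies to predictions and generated
#' corpora).
#'
#' @param corpus An annotated corpus (tibble with `seq_id`, `labels`).
#' @return A tibble with columns `seq_id`, `start`, `end`, `label`.
#' @export
corpus_segments <- function(corpus) {
  purrr::map2_dfr(corpus$seq_id, corpus$labels, function(id, lab) {
    seg <- labels_to_segments(lab)
    if (nrow(seg) == 0L) return(NULL)
    tibble::tibble(seq_id = id, start = seg$start, end = seg$end, label = "linker")
  })
}

#' Write a linker segment table as an annotation TSV
#'
#' @param segments A data frame with columns `seq_id`, `start`, `end`, `label`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(segments, path) {
  readr::write_tsv(segments[, c("seq_id", "start", "end", "label")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write per-residue predictions with a derived segment block
#'
#' Writes a prediction result as a per-residue TSV (`seq_id`, `pos`,
#' `linker_vote_fraction`, `label`) followed by a `#SEGMENTS` marker and the
#' maximal predicted linker runs in annotation-TSV format. The segment block
#' round-trips through [read_annotations()].
#'
#' @param result A prediction tibble as returned by [predict_votes()]
#'   (columns `seq_id`, `pos`, `vote_fraction`, `label`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(result, path) {
  stopifnot(all(c("seq_id", "pos", "vote_fraction", "label") %in% names(result)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  per_res <- tibble::tibble(
    seq_id = result$seq_id, pos = result$pos,
    linker_vote_fraction = result$vote_fraction, label = result$label
  )
  writeLines(format_tsv_lines(per_res), con)
  writeLines("#SEGMENTS", con)
  segs <- result |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::group_map(function(d, key) {
      seg <- labels_to_segments(d$label[order(d$pos)])
      if (nrow(seg) == 0L) return(NULL)
      tibble::tibble(seq_id = key$seq_id, start = seg$start, end = seg$end,
                     label = "linker")
    }) |>
    dplyr::bind_rows()
  if (nrow(segs) == 0L) {
    segs <- tibble::tibble(seq_id = character(), start = integer(),
                           end = integer(), label = character())
  }
  writeLines(format_tsv_lines(segs), con)
  invisible(path)
}

format_tsv_lines <- function(df) {
  header <- paste(names(df), collapse = "\t")
  if (nrow(df) == 0L) return(header)
  body <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
  c(header, body)
}
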