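# Small, strongly divergent corpora for fast pipeline tests. The divergence
# multiplier is raised so that even tiny corpora carry usable signal.
make_corpus <- function(n = 12, seed = 1, divergence = 4, ...) {
  generate_corpus(n, divergence_multiplier = divergence, seed = seed, ...)
}

# Hand-buildable annotated corpus from explicit residues + label strings
manual_corpus <- function(residues, label_strings, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(residues))
  labels <- lapply(label_strings, function(s) as.integer(strsplit(s, "")[[1]]))
  stopifnot(all(nchar(residues) == lengths(labels)))
  tibble::tibble(seq_id = ids, residues = residues, labels = labels)
}

# Brute-force reference for window_average: per-position loop over the
# clipped window
brute_window <- function(m, w) {
  h <- (w - 1) / 2
  L <- nrow(m)
  out <- matrix(NA_real_, L, ncol(m))
  for (j in seq_len(L)) {
    idx <- max(1, j - h):min(L, j + h)
    out[j, ] <- colMeans(m[idx, , drop = FALSE])
  }
  colnames(out) <- colnames(m)
  out
}

# Separable toy task: class decided by the sign of feature 1 (plus noise
# features), per the generating-rule oracle
toy_task <- function(n = 200, p_noise = 4, seed = 99) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * (1 + p_noise)), n)
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    list(x = x, y = as.integer(x[, 1] > 0))
  })
}

write_tmp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

write_tmp_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
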