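test_that("generated sequences alternate domain-linker-domain within bounds", {
  corp <- generate_corpus(15, domains_per_sequence = 3, seed = 21)
  segs <- attr(corp, "segments")
  # exactly domains_per_sequence - 1 linkers per sequence
  expect_equal(unname(table(segs$seq_id)), rep(2L, 15), ignore_attr = TRUE)
  for (i in seq_len(nrow(corp))) {
    r <- rle(corp$labels[[i]])
    expect_equal(r$values[1], 0L)                      # starts with a domain
    expect_equal(r$values[length(r$values)], 0L)       # ends with a domain
    expect_equal(r$values, rep(c(0L, 1L), length.out = length(r$values)))
    dom <- r$lengths[r$values == 0L]
    link <- r$lengths[r$values == 1L]
    expect_true(all(dom >= 25 & dom <= 500))
    expect_true(all(link >= 10 & link <= 100))
  }
  # labels and truth segment table agree
  expect_equal(corpus_segments(corp)[, c("seq_id", "start", "end")],
               segs[, c("seq_id", "start", "end")])
})

test_that("generation is byte-identical under a fixed seed", {
  c1 <- generate_corpus(6, seed = 33, divergence_multiplier = 2)
  c2 <- generate_corpus(6, seed = 33, divergence_multiplier = 2)
  expect_identical(c1$residues, c2$residues)
  expect_identical(attr(c1, "segments"), attr(c2, "segments"))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(c1, f1); write_fasta(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  c3 <- generate_corpus(6, seed = 34, divergence_multiplier = 2)
  expect_false(identical(c1$residues, c3$residues))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_corpus(2, seed = 99)); b <- runif(1)
  expect_identical(a, b)
})

test_that("corpus statistics match hand counts on a toy corpus", {
  corp <- manual_corpus("AAAGGAAA", "00011000")
  st <- corpus_stats(corp)
  expect_equal(st$n_domain_segments, 2L)
  expect_equal(st$n_linker_segments, 1L)
  expect_equal(st$mean_domain_length, 3)
  expect_equal(st$mean_linker_length, 2)
  expect_equal(st$linker_residue_share, 100 * 2 / 8)
  expect_equal(st$domain_residue_share + st$linker_residue_share, 100)
  empty <- corpus_stats(tibble::tibble(seq_id = character(),
                                       residues = character(),
                                       labels = list()))
  expect_equal(empty$n_sequences, 0L)
})

test_that("residue-share arithmetic reproduces printed dataset statistics", {
  sh <- segment_residue_shares(334, 147.1, 183, 12.7)
  expect_equal(sh$domain_residue_share, 95.5, tolerance = 0.001)
  sh2 <- segment_residue_shares(794, 122.1, 486, 35.8)
  expect_equal(sh2$domain_residue_share, 85, tolerance = 0.006)
})

test_that("empirical compositions converge to the configured laws", {
  corp <- generate_corpus(500, seed = 55)
  cfg <- attr(corp, "config")
  comp <- corpus_compositions(corp)
  expect_equal(stats::setNames(comp$linker_pct, comp$aa),
               cfg$linker_composition[comp$aa], tolerance = 0.5,
               ignore_attr = TRUE)
  expect_equal(stats::setNames(comp$domain_pct, comp$aa),
               cfg$domain_composition[comp$aa], tolerance = 0.5,
               ignore_attr = TRUE)
  # realized mean segment lengths track the truncated laws (sampling error);
  # the linker law's lower truncation at 10 raises its mean above 12.7
  st <- corpus_stats(corp)
  expect_equal(st$mean_domain_length, 147.1, tolerance = 0.05)
  expect_gt(st$mean_linker_length, 12.7)
  expect_lt(st$mean_linker_length, 25)
})

test_that("divergence amplification scales log-ratios and renormalizes", {
  l <- .default_composition("linker"); d <- .default_composition("domain")
  out <- diverge_compositions(l, d, 3)
  expect_equal(sum(out$linker), 100)
  expect_equal(sum(out$domain), 100)
  # log-ratio triples up to a shared renormalization constant
  r1 <- log(l / d)
  r3 <- log(out$linker / out$domain)
  expect_equal(unname(diff(range(r3 - 3 * r1))), 0, tolerance = 1e-9)
  ident <- diverge_compositions(l, d, 1)
  expect_equal(as.numeric(ident$linker), as.numeric(100 * l / sum(l)))
})

test_that("infeasible truncation bounds error out", {
  expect_error(generate_corpus(2, linker_length_mean = 0.01, seed = 1),
               "no mass")
  expect_error(generate_corpus(2, domain_length_mean = 1e6, seed = 1),
               "no mass")
  expect_error(generate_corpus(2, linker_composition = c(A = 50, G = 50),
                               seed = 1), "20 standard")
})
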