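test_that("generated precursors realize their designed duplex", {
  for (s in c(1, 5, 9)) {
    spec <- hairpin_spec(seed = s, signature_motif = "AUG")
    p <- make_precursor(spec)
    d <- analyze_duplex(fold_profile(p$seq), p$mature_span)
    expect_equal(d$mismatches, spec$stem_mismatches)
    expect_true(d$same_arm)
    expect_true(d$star_contiguous)
    expect_false(d$overlaps_loop)
    # planted signature density: 4 copies in a ~100 nt precursor
    expect_gte(r_value(p$seq, "AUG"), 2.5)
    # truth coordinates point at the actual motif copies
    for (st in p$motif_starts) {
      expect_equal(substring(p$seq, st, st + 2), "AUG")
    }
  }
})

test_that("generation is bit-reproducible under a fixed seed", {
  spec <- hairpin_spec(seed = 33, signature_motif = "UUG")
  expect_identical(make_precursor(spec), make_precursor(spec))
  expect_false(identical(make_precursor(spec),
                         make_precursor(hairpin_spec(seed = 34,
                                                     signature_motif = "UUG"))))
  d1 <- make_decoys(4, kind = "random", seed = 8, lengths = 120)
  d2 <- make_decoys(4, kind = "random", seed = 8, lengths = 120)
  expect_identical(d1, d2)
  c1 <- make_corpus(n_planted = 2, n_decoys = 3, seed = 12)
  c2 <- make_corpus(n_planted = 2, n_decoys = 3, seed = 12)
  expect_identical(c1, c2)
})

test_that("infeasible specs are rejected", {
  expect_error(make_precursor(hairpin_spec(flank_len = 2L,
                                           signature_motif = "UUG",
                                           signature_copies = 3L)),
               "tail capacity")
  expect_error(hairpin_spec(flank_len = 230L), "55-505")
  expect_error(hairpin_spec(stem_mismatches = 2L, sub_sites = c(5L)),
               "length")
})

test_that("families share the planted motif at qualifying density", {
  fam <- make_family(4, "UUG", seed = 41)
  seqs <- vapply(fam, `[[`, character(1), "seq")
  expect_length(seqs, 4L)
  expect_true(all(vapply(seqs, r_value, numeric(1), motif = "UUG") >= 2.5))
  sig <- family_signature(seqs)
  expect_equal(sig$motif, "UUG")

  # two families with different motifs are distinguished in the catalog
  fam2 <- make_family(4, "ACG", seed = 42)
  cat <- build_catalog(list(A = seqs,
                            B = vapply(fam2, `[[`, character(1), "seq")))
  expect_equal(cat$motif[cat$family == "A"], "UUG")
  expect_equal(cat$motif[cat$family == "B"], "ACG")

  # single-member family exercises the max-R path
  one <- make_family(1, "UUG", seed = 43)
  expect_length(one, 1L)
})

test_that("EST embedding records recoverable truth coordinates", {
  p <- make_precursor(hairpin_spec(seed = 51, signature_motif = "UUG"))
  emb <- embed_in_est(p, flank_len = 80, seed = 52)
  expect_equal(nchar(emb$seq), nchar(p$seq) + 160)
  expect_equal(substring(emb$seq, emb$precursor_span[1],
                         emb$precursor_span[2]), p$seq)
  mature <- substring(p$seq, p$mature_span[1], p$mature_span[2])
  expect_equal(substring(emb$seq, emb$mature_span[1], emb$mature_span[2]),
               mature)

  # the homology scan finds the planted mature at the truth span
  hits <- scan_homologs(setNames(mature, "syn-miR1a"),
                        setNames(emb$seq, "est1"))
  expect_true(any(hits$sstart == emb$mature_span[1] &
                    hits$send == emb$mature_span[2] &
                    hits$mismatches == 0 & hits$strand == "+"))

  # minus-strand embedding is recovered with strand awareness
  emb2 <- embed_in_est(p, flank_len = 80, seed = 53, strand = "-")
  hits2 <- scan_homologs(setNames(mature, "syn-miR1a"),
                         setNames(emb2$seq, "est2"))
  expect_true(any(hits2$sstart == emb2$mature_span[1] &
                    hits2$send == emb2$mature_span[2] &
                    hits2$strand == "-" & hits2$mismatches == 0))

  # zero flank keeps the subject equal to the precursor
  emb0 <- embed_in_est(p, flank_len = 0, seed = 54)
  expect_equal(emb0$seq, p$seq)
})

test_that("dinucleotide shuffles preserve dinucleotide counts", {
  set.seed(61)
  for (trial in 1:10) {
    s <- random_rna(sample(50:150, 1))
    sh <- dinucleotide_shuffle(s)
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_equal(nchar(sh), nchar(s))
  }
  # shuffling changes the sequence for non-trivial inputs
  s <- random_rna(200)
  set.seed(62)
  expect_false(dinucleotide_shuffle(s) == s)
})

test_that("decoy generators produce the requested negatives", {
  tmpl <- vapply(1:3, function(k) {
    make_precursor(hairpin_spec(seed = 70 + k,
                                signature_motif = "UUG"))$seq
  }, character(1))
  sh <- make_decoys(6, kind = "shuffled", seed = 71, templates = tmpl)
  expect_length(sh, 6L)
  for (k in seq_along(sh)) {
    expect_equal(dinuc_counts(sh[[k]]),
                 dinuc_counts(tmpl[[((k - 1) %% 3) + 1]]))
  }
  expect_length(make_decoys(0, kind = "random", seed = 1), 0L)

  set.seed(72)
  protein <- paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                            "I", "L", "K", "M", "F", "P", "S", "T", "W",
                            "Y", "V"), 50, replace = TRUE), collapse = "")
  cod <- make_decoys(4, kind = "coding", seed = 73, proteins = protein,
                     lengths = 140)
  res <- coding_filter(cod, proteins = protein)
  expect_length(res$rejected, 4L)
})

test_that("the corpus ties queries, subjects, catalog and truth together", {
  corpus <- make_corpus(n_planted = 4, n_decoys = 6, seed = 81)
  expect_length(corpus$queries, 4L)
  expect_length(corpus$subjects, 10L)
  expect_equal(nrow(corpus$truth), 4L)
  # every planted mature is present in its subject at the truth span
  for (k in seq_len(nrow(corpus$truth))) {
    tr <- corpus$truth[k, ]
    sub <- corpus$subjects[[tr$subject_id]]
    frag <- substring(sub, tr$mature_start, tr$mature_end)
    if (tr$strand == "-") frag <- rev_comp(frag)
    expect_equal(frag, tr$mature_seq)
  }
  # family members carry the family signature found by the catalog
  cat <- build_catalog(corpus$families)
  expect_false(any(is.na(cat$motif)))
})
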