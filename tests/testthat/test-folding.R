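test_that("MFE folding matches exhaustive enumeration on random sequences", {
  set.seed(101)
  for (trial in 1:40) {
    seq <- random_rna(sample(5:15, 1))
    oracle <- oracle_fold(seq)
    m <- fold_mfe(seq)
    expect_equal(m$mfe, oracle$mfe, tolerance = 1e-12, info = seq)
    # returned structure attains the reported energy under the model
    pt <- pair_table(m$structure)
    chars <- strsplit(seq, "")[[1]]
    pairs <- which(pt > seq_along(pt))
    e <- if (length(pairs)) {
      sum(vapply(pairs, function(i) {
        pr <- paste0(chars[i], chars[pt[i]])
        if (pr %in% c("GC", "CG")) -3 else if (pr %in% c("AU", "UA")) -2
        else -1
      }, numeric(1)))
    } else 0
    expect_equal(e, m$mfe, tolerance = 1e-12)
    # constraints: complementarity and minimum loop
    for (i in pairs) {
      expect_true(oracle_pairable(chars[i], chars[pt[i]]))
      expect_gt(pt[i] - i, 3)
    }
  }
})

test_that("simple folds behave as expected", {
  m <- fold_mfe("GGGAAACCC")
  expect_equal(m$structure, "(((...)))")
  expect_equal(m$mfe, -9)
  expect_equal(fold_mfe("AAAAAA"),
               list(structure = "......", mfe = 0, n_pairs = 0L))
  expect_error(fold_mfe("ACGX"), "invalid character")
})

test_that("pair probabilities match exhaustive Boltzmann enumeration", {
  set.seed(202)
  for (trial in 1:40) {
    n <- sample(5:15, 1)
    seq <- random_rna(n)
    oracle <- oracle_fold(seq)
    pp <- pair_probabilities(seq)
    impl <- matrix(0, n, n)
    if (nrow(pp)) {
      for (r in seq_len(nrow(pp))) impl[pp$i[r], pp$j[r]] <- pp$p[r]
    }
    expect_lt(max(abs(impl - oracle$pair_prob)), 1e-9)
  }
})

test_that("pair probability mass per position never exceeds one", {
  set.seed(303)
  for (trial in 1:10) {
    seq <- random_rna(sample(30:80, 1))
    pp <- pair_probabilities(seq)
    n <- nchar(seq)
    mass <- numeric(n)
    for (r in seq_len(nrow(pp))) {
      mass[pp$i[r]] <- mass[pp$i[r]] + pp$p[r]
      mass[pp$j[r]] <- mass[pp$j[r]] + pp$p[r]
    }
    expect_true(all(mass <= 1 + 1e-9))
  }
})

test_that("every MFE pair carries positive ensemble probability", {
  set.seed(404)
  for (trial in 1:10) {
    seq <- random_rna(40)
    prof <- fold_profile(seq)
    pt <- pair_table(prof$structure)
    pp <- prof$pair_prob
    for (i in which(pt > seq_along(pt))) {
      p <- pp$p[pp$i == i & pp$j == pt[i]]
      expect_true(length(p) == 1 && p > 0)
    }
  }
})

test_that("in the low-temperature limit probabilities concentrate on the MFE structure", {
  seq <- "GGGGAAAACCCC"  # unique MFE structure
  cold <- folding_params(rt = 0.01)
  pp <- pair_probabilities(seq, cold)
  pt <- pair_table(fold_mfe(seq, cold)$structure)
  for (r in seq_len(nrow(pp))) {
    is_mfe_pair <- pt[pp$i[r]] == pp$j[r]
    expect_equal(pp$p[r], as.numeric(is_mfe_pair), tolerance = 1e-6)
  }
})

test_that("duplex analysis reads the mature/star geometry off the structure", {
  # perfect 8-pair hairpin: "((((((((....))))))))"
  seq <- paste0("GGGGGGGG", "AAAA", "CCCCCCCC")
  prof <- fold_profile(seq)
  expect_equal(prof$structure, "((((((((....))))))))")
  d <- analyze_duplex(prof, c(1, 8))
  expect_equal(d$star_span, c(13, 20))
  expect_equal(d$n_pairs, 8L)
  expect_equal(d$mismatches, 0L)
  expect_true(d$same_arm)
  expect_true(d$star_contiguous)
  expect_false(d$overlaps_loop)

  # mature spanning the terminal loop
  d2 <- analyze_duplex(prof, c(7, 15))
  expect_true(d2$overlaps_loop)
  expect_false(d2$same_arm)

  expect_error(analyze_duplex(prof, c(10, 9)), "start <= end")
  expect_error(analyze_duplex(prof, c(0, 5)), "bounds")
})

test_that("unpaired mature positions count as duplex mismatches", {
  p <- make_precursor(hairpin_spec(seed = 7, signature_motif = "UUG"))
  d <- analyze_duplex(fold_profile(p$seq), p$mature_span)
  expect_equal(d$mismatches, p$spec$stem_mismatches)
  p6 <- make_precursor(ablation_spec(seed = 1))
  d6 <- analyze_duplex(fold_profile(p6$seq), p6$mature_span)
  expect_equal(d6$mismatches, 5L)
})

test_that("a mock backend satisfies the same profile contract", {
  mock <- function(seq) {
    list(structure = strrep(".", nchar(seq)), mfe = 0,
         pair_prob = data.frame(i = integer(), j = integer(),
                                p = numeric()))
  }
  prof <- fold_profile("ACGUACGU", backend = mock)
  expect_s3_class(prof, "folding_profile")
  expect_equal(nchar(prof$structure), 8L)
  d <- compute_descriptors(prof)
  expect_equal(d$npb, 0)
  expect_equal(d$nq, 0)
})

test_that("the RNAfold backend honours the backend contract when available", {
  skip_if(Sys.which("RNAfold") == "", "RNAfold not on PATH")
  be <- vienna_backend()
  prof <- fold_profile("GGGGGAAAAAAACCCCC", backend = be)
  expect_equal(nchar(prof$structure), 17L)
  expect_lt(prof$mfe, 0)
  expect_true(all(prof$pair_prob$p > 0 & prof$pair_prob$p <= 1))
  expect_true(all(prof$pair_prob$i < prof$pair_prob$j))
})
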