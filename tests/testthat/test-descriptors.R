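make_profile <- function(seq, structure, mfe, pair_prob) {
  structure(list(seq = seq, structure = structure, mfe = mfe,
                 pair_prob = pair_prob), class = "folding_profile")
}

test_that("descriptor definitions reproduce hand-computed values", {
  # AMFE and MFEI at L = 100, GC = 50%
  seq <- strrep("GCAU", 25)
  prof <- make_profile(seq, strrep(".", 100), -50,
                       data.frame(i = integer(), j = integer(),
                                  p = numeric()))
  d <- compute_descriptors(prof)
  expect_equal(d$amfe, 50)
  expect_equal(d$mfei, 1)
  expect_equal(d$au_pct + d$gc_pct, 100)

  # one feasible pair at p = 0.5 in a 10-nt sequence
  prof2 <- make_profile("GAAAAAAAAC", "..........", 0,
                        data.frame(i = 1L, j = 10L, p = 0.5))
  d2 <- compute_descriptors(prof2)
  expect_equal(d2$nq, 0.05)
  expect_equal(d2$nd, 0.025)

  # three pairs over nine bases
  prof3 <- make_profile("GGGAAACCC", "(((...)))", -9,
                        data.frame(i = 1:3, j = 9:7, p = rep(1, 3)))
  d3 <- compute_descriptors(prof3)
  expect_equal(d3$npb, 1 / 3)
  # deterministic ensemble: all probabilities 0 or 1 gives zero entropy
  expect_equal(d3$nq, 0)
  expect_equal(d3$nd, 0)
})

test_that("MFEI is missing when GC is zero", {
  prof <- make_profile("AUAUAUAUAU", "..........", 0,
                       data.frame(i = integer(), j = integer(),
                                  p = numeric()))
  d <- compute_descriptors(prof)
  expect_true(is.na(d$mfei))
  expect_false(check_descriptors(d, viridiplantae_cutoffs())["mfei_ok"])
})

test_that("cutoff derivation uses interpolated order statistics", {
  # two-sided: 1000 uniform lengths, checked against a sort-based oracle
  set.seed(55)
  L <- runif(1000, 50, 500)
  tab <- data.frame(L = L, au_pct = runif(1000, 20, 80),
                    mfei = seq_len(1000), nq = runif(1000),
                    nd = runif(1000), npb = runif(1000, 0, 0.5))
  cu <- derive_cutoffs(tab)
  s <- sort(L)
  # type-7 interpolation oracle at p = 0.005 / 0.995
  q7 <- function(s, p) {
    h <- (length(s) - 1) * p + 1
    s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
  }
  expect_equal(cu$length[1], q7(s, 0.005))
  expect_equal(cu$length[2], q7(s, 0.995))

  # one-sided: 200 MFEI values 1..200 give interpolated first percentile
  tab2 <- data.frame(L = rep(100, 200), au_pct = rep(50, 200),
                     mfei = 1:200, nq = rep(0.1, 200), nd = rep(0.05, 200),
                     npb = rep(0.3, 200))
  expect_equal(derive_cutoffs(tab2)$mfei_min, 2.99)

  # degenerate table: every interval collapses to the constant
  tab3 <- data.frame(L = rep(90, 10), au_pct = rep(44, 10),
                     mfei = rep(1.2, 10), nq = rep(0.3, 10),
                     nd = rep(0.1, 10), npb = rep(0.35, 10))
  cu3 <- derive_cutoffs(tab3)
  expect_equal(cu3$length, c(90, 90))
  expect_equal(cu3$mfei_min, 1.2)
  expect_equal(cu3$nq_max, 0.3)

  expect_error(derive_cutoffs(tab3[1, , drop = FALSE]), "at least 2")
})

test_that("higher coverage never narrows an interval", {
  set.seed(66)
  tab <- data.frame(L = rnorm(400, 150, 40), au_pct = runif(400, 20, 80),
                    mfei = rexp(400), nq = runif(400), nd = runif(400),
                    npb = runif(400, 0, 0.5))
  covs <- c(0.5, 0.8, 0.9, 0.99)
  cus <- lapply(covs, function(cv) derive_cutoffs(tab, coverage = cv))
  for (k in 2:length(cus)) {
    expect_lte(cus[[k]]$length[1], cus[[k - 1]]$length[1])
    expect_gte(cus[[k]]$length[2], cus[[k - 1]]$length[2])
    expect_lte(cus[[k]]$mfei_min, cus[[k - 1]]$mfei_min)
    expect_gte(cus[[k]]$nq_max, cus[[k - 1]]$nq_max)
    expect_gte(cus[[k]]$nd_max, cus[[k - 1]]$nd_max)
    expect_lte(cus[[k]]$npb_min, cus[[k - 1]]$npb_min)
  }
})

test_that("boundary descriptor values pass the published cutoffs", {
  cu <- viridiplantae_cutoffs()
  base <- list(L = 100, au_pct = 50, gc_pct = 50, mfe = -50, amfe = 50,
               mfei = 0.41, nq = 0.45, nd = 0.15, npb = 0.25)
  class(base) <- "descriptor_set"
  chk <- check_descriptors(base, cu)
  expect_true(all(chk))

  worse <- base
  worse$nq <- 0.46
  expect_false(check_descriptors(worse, cu)["nq_ok"])

  au_edge <- base
  au_edge$au_pct <- 22
  expect_true(check_descriptors(au_edge, cu)["au_ok"])

  # the alternative published AU range is stricter at the low end
  expect_false(check_descriptors(au_edge,
                                 viridiplantae_cutoffs(au = "results"))["au_ok"])
})

test_that("descriptors of generated hairpins fall inside population cutoffs", {
  cu <- fixture_cutoffs()
  for (s in 1:10) {
    p <- make_precursor(hairpin_spec(seed = 400 + s,
                                     signature_motif = "AUG"))
    d <- compute_descriptors(fold_profile(p$seq))
    expect_true(all(check_descriptors(d, cu)), info = paste("seed", s))
  }
})

test_that("cutoff sets survive a JSON round-trip", {
  cu <- fixture_cutoffs()
  path <- tempfile(fileext = ".json")
  write_cutoffs(cu, path)
  back <- read_cutoffs(path)
  expect_equal(unclass(back), unclass(cu))
})
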