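# Genotype model: allele frequencies, mismatch counting, probability of
# identity, and sample matching.

test_that("allele frequencies are direct normalised counts", {
  panel <- locus_panel("L1")
  g <- gstack(g1(1, 1, panel = panel), g1(1, 2, panel = panel), ids = c("a", "b"))
  f <- estimate_allele_frequencies(g, panel)
  expect_equal(unname(unclass(f)$L1[c("1", "2")]), c(0.75, 0.25))

  f1 <- estimate_allele_frequencies(g1(1, 2, panel = panel), panel)
  expect_equal(unname(unclass(f1)$L1), c(0.5, 0.5))

  expect_error(estimate_allele_frequencies(matrix(NA_integer_, 0, 2), panel))
})

test_that("frequency estimates recover the truth within binomial error", {
  set.seed(11)
  panel <- default_panel(5, 2)
  freqs <- uniform_freqs(panel, k = 4)
  g <- draw_genos(100, freqs, panel)
  est <- estimate_allele_frequencies(g, panel)
  for (l in panel$loci) {
    p_hat <- unclass(est)[[l]]
    # 3 binomial SE on 200 allele draws at p = 0.25
    se <- sqrt(0.25 * 0.75 / 200)
    expect_true(all(abs(p_hat - 0.25) < 3 * se + 1e-12))
  }
})

test_that("loci with no observations are flagged absent", {
  panel <- locus_panel(c("L1", "L2"))
  g <- g1(1, 2, NA, NA, panel = panel)
  f <- estimate_allele_frequencies(g, panel)
  expect_identical(attr(f, "absent"), "L2")
  expect_length(unclass(f)$L2, 0)
})

test_that("dyad mismatches count loci with no shared allele, skipping missing", {
  panel <- locus_panel("L1")
  expect_equal(pair_mismatches(g1(1, 2, panel = panel), g1(2, 3, panel = panel), panel), 0L)
  expect_equal(pair_mismatches(g1(1, 2, panel = panel), g1(3, 4, panel = panel), panel), 1L)
  expect_equal(pair_mismatches(g1(1, 2, panel = panel), g1(NA, NA, panel = panel), panel), 0L)
})

test_that("trio mismatches require one allele from each parent", {
  panel <- locus_panel("L1")
  expect_equal(trio_mismatches(g1(1, 2, panel = panel), g1(1, 1, panel = panel),
                               g1(2, 2, panel = panel), panel), 0L)
  expect_equal(trio_mismatches(g1(1, 1, panel = panel), g1(2, 2, panel = panel),
                               g1(1, 1, panel = panel), panel), 1L)
  # joint failure despite dyad compatibility: o needs 1 from both parents
  expect_equal(trio_mismatches(g1(1, 1, panel = panel), g1(1, 2, panel = panel),
                               g1(2, 3, panel = panel), panel), 1L)
})

test_that("mismatch counts are order-invariant and trio dominates dyads", {
  set.seed(21)
  panel <- default_panel(4, 2)
  for (rep in 1:200) {
    o <- draw_genos(1, uniform_freqs(panel, 3), panel, ids = "o")
    m <- draw_genos(1, uniform_freqs(panel, 3), panel, ids = "m")
    f <- draw_genos(1, uniform_freqs(panel, 3), panel, ids = "f")
    tm <- trio_mismatches(o, m, f, panel)
    expect_identical(tm, trio_mismatches(o, f, m, panel))
    expect_gte(tm, max(pair_mismatches(o, m, panel), pair_mismatches(o, f, panel)))
    # allele-order permutation within a genotype cannot matter: genotypes are
    # stored sorted, so swapping input columns yields identical rows
    swapped <- o[, as.vector(rbind(seq(2, 8, 2), seq(1, 7, 2))), drop = FALSE]
    colnames(swapped) <- colnames(o)
    expect_identical(as_genotypes(swapped, panel), o)
  }
})

test_that("probability of identity matches enumeration and decreases with loci", {
  panel1 <- locus_panel("L1")
  f2 <- structure(list(L1 = c("1" = 0.5, "2" = 0.5)),
                  class = "allele_freq_table", absent = character(0))
  # enumeration: genotype probs (0.25, 0.5, 0.25), PI = sum of squares
  expect_equal(probability_of_identity(f2), 0.375)

  f1 <- structure(list(L1 = c("1" = 1)),
                  class = "allele_freq_table", absent = character(0))
  expect_equal(probability_of_identity(f1), 1.0)

  set.seed(5)
  panel <- default_panel(6, 2)
  freqs <- random_freqs(panel, k = 5)
  pis <- vapply(seq_along(panel$loci), function(k) {
    probability_of_identity(freqs, panel$loci[seq_len(k)])
  }, numeric(1))
  expect_true(all(diff(pis) < 0))
  expect_error(probability_of_identity(freqs, character(0)))
})

test_that("sample matching screens, resolves and creates individuals", {
  panel <- default_panel(8, 3)
  set.seed(9)
  cat_g <- draw_genos(5, uniform_freqs(panel, 6), panel,
                      ids = sprintf("C%02d", 1:5))
  # identical to a catalogued bear: resolves to it
  s <- cat_g[2, , drop = FALSE]
  expect_identical(match_sample(s, cat_g, panel),
                   list(status = "resolved", id = "C02"))
  # missing one screening locus: discarded
  s_miss <- s
  s_miss[1, 1:2] <- NA
  expect_identical(match_sample(s_miss, cat_g, panel)$status, "discard")
  # novel genotype: new individual
  s_new <- s
  s_new[1, ] <- rep(c(9L, 9L), 8)
  expect_identical(match_sample(s_new, cat_g, panel)$status, "new")
})

test_that("zero-error sampling partitions samples exactly by true individual", {
  p <- sim_params(years = 2014:2020, n0 = 40, seed = 31,
                  error_rate = 0, missing_rate = 0)
  tr <- simulate_population(p)
  ss <- simulate_sampling(tr)
  catg <- build_catalogue(ss$samples, ss$genotypes, tr$panel,
                          window = c(2019, 2020))
  map <- catg$sample_assignments
  expect_false(any(map == "discarded"))
  # the sample -> individual map must be a refinement-free relabelling of
  # the true source: same truth id <=> same catalogue id
  truth_of <- stats::setNames(ss$samples$true_id, ss$samples$sample_id)
  split_truth <- split(names(map), map)
  for (grp in split_truth) {
    expect_length(unique(truth_of[grp]), 1L)
  }
  expect_equal(length(split_truth), length(unique(truth_of)))
})
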