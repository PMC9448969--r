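# Likelihood engine, Delta calibration and the assignment steps.

test_that("transition probabilities match hand enumeration", {
  panel <- locus_panel("L1")
  f <- structure(list(L1 = c("1" = 0.5, "2" = 0.5)),
                 class = "allele_freq_table", absent = character(0))
  # mother (1,1), offspring (1,1): second allele drawn at p1 = 0.5
  expect_equal(transition_prob(c(1, 1), c(1, 1), freqs = f, locus = "L1", e = 0), 0.5)
  # exclusion at e = 0
  expect_equal(transition_prob(c(1, 1), c(2, 2), freqs = f, locus = "L1", e = 0), 0)
  # error absorbs the exclusion
  expect_gt(transition_prob(c(1, 1), c(2, 2), freqs = f, locus = "L1", e = 0.01), 0)
  # trio: o=(1,2) from m=(1,1), f=(2,2) is certain at e = 0
  expect_equal(transition_prob(c(1, 2), c(1, 1), c(2, 2), freqs = f,
                               locus = "L1", e = 0), 1)
})

test_that("LOD scores follow the closed form and empty candidates score zero", {
  panel <- locus_panel("L1")
  f <- structure(list(L1 = c("1" = 0.5, "2" = 0.5)),
                 class = "allele_freq_table", absent = character(0))
  o <- g1(1, 1, panel = panel)
  m <- g1(1, 1, panel = panel)
  # LR = 0.5 / 0.25 = 2
  expect_equal(lod_score(o, mother = m, freqs = f, panel = panel, e = 0), log(2))
  # all-missing candidate: empty product
  expect_equal(lod_score(o, mother = g1(NA, NA, panel = panel),
                         freqs = f, panel = panel, e = 0), 0)
})

test_that("Delta calibration is deterministic and ordered", {
  set.seed(2)
  panel <- default_panel(8, 3)
  freqs <- random_freqs(panel, k = 5)
  cfg <- assignment_config(n_simulation_cycles = 400,
                           n_candidates_per_offspring = 30)
  thr1 <- calibrate_delta(cfg, freqs, seed = 99)
  thr2 <- calibrate_delta(cfg, freqs, seed = 99)
  expect_identical(unclass(thr1), unclass(thr2))
  expect_true(all(thr1[, "relaxed"] <= thr1[, "strict"]))
  expect_true(all(is.finite(thr1)))
})

test_that("reduced calibration agrees with a larger run within noise", {
  set.seed(3)
  panel <- default_panel(21, 6)
  freqs <- random_freqs(panel, k = 6)
  cfg_small <- assignment_config(n_simulation_cycles = 1000)
  cfg_large <- assignment_config(n_simulation_cycles = 4000)
  t_small <- calibrate_delta(cfg_small, freqs, seed = 7)
  t_large <- calibrate_delta(cfg_large, freqs, seed = 8)
  # with 21 informative loci both runs separate true parents clearly;
  # thresholds are on the same scale (no order-of-magnitude drift)
  expect_true(all(abs(t_small - t_large) < 6))
})

test_that("a complete candidate set yields the true pair; hard limits hold", {
  set.seed(41)
  panel <- default_panel(12, 4)
  freqs <- random_freqs(panel, k = 6)
  cfg <- assignment_config(error_rate = 0, n_simulation_cycles = 400,
                           n_candidates_per_offspring = 30)
  thr <- calibrate_delta(cfg, freqs, seed = 5)
  mo <- draw_genos(1, freqs, panel, ids = "M01")
  fa <- draw_genos(1, freqs, panel, ids = "F01")
  kid <- mendel_child(mo, fa, panel)
  others_m <- draw_genos(5, freqs, panel, ids = sprintf("M%02d", 2:6))
  others_f <- draw_genos(5, freqs, panel, ids = sprintf("F%02d", 2:6))
  res <- assign_parent_pair(kid, rbind(mo, others_m), rbind(fa, others_f),
                            thr, cfg, freqs, panel)
  expect_identical(res$mother, "M01")
  expect_identical(res$father, "F01")
  expect_identical(res$route, "trio-strict")
  expect_equal(res$mismatches, 0L)

  # a trio with >= 2 mismatches is never accepted, whatever Delta
  far <- mo
  far[1, 1:4] <- c(6L, 6L, 6L, 6L)  # two exclusion loci vs the kid
  fa2 <- fa
  fa2[1, 1:4] <- c(5L, 5L, 5L, 5L)
  kid2 <- kid
  kid2[1, 1:4] <- c(5L, 5L, 5L, 5L)  # mother cannot supply allele 5 twice
  expect_gte(trio_mismatches(kid2, far, fa2, panel), 2L)
  res2 <- assign_parent_pair(kid2, far, fa2, thr, cfg, freqs, panel)
  expect_identical(res2$route, "none")
})

test_that("single-parent assignment enforces zero mismatches", {
  set.seed(43)
  panel <- default_panel(12, 4)
  freqs <- random_freqs(panel, k = 6)
  cfg <- assignment_config(error_rate = 0, n_simulation_cycles = 400,
                           n_candidates_per_offspring = 30)
  thr <- calibrate_delta(cfg, freqs, seed = 5)
  mo <- draw_genos(1, freqs, panel, ids = "M01")
  fa <- draw_genos(1, freqs, panel, ids = "F01")
  kid <- mendel_child(mo, fa, panel)
  # candidate with one forced mismatch is rejected
  bad <- mo
  bad[1, 1:2] <- c(9L, 9L)
  kid_mm <- kid
  kid_mm[1, 1:2] <- c(8L, 8L)
  res <- assign_single_parent(kid_mm, bad, thr, cfg, freqs, panel)
  expect_true(is.na(res$parent))
  # empty candidate set is 'none', not an error
  res0 <- assign_single_parent(kid, mo[0, , drop = FALSE], thr, cfg, freqs, panel)
  expect_true(is.na(res0$parent))
})

test_that("the true single parent is recovered from many candidates", {
  set.seed(47)
  panel <- default_panel(21, 6)
  freqs <- random_freqs(panel, k = 6)
  cfg <- assignment_config(error_rate = 0, n_simulation_cycles = 1500)
  thr <- calibrate_delta(cfg, freqs, seed = 13)
  hits <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    mo <- draw_genos(1, freqs, panel, ids = "TRUE-M")
    fa <- draw_genos(1, freqs, panel, ids = "X-F")
    kid <- mendel_child(mo, fa, panel)
    cands <- rbind(mo, draw_genos(149, freqs, panel,
                                  ids = sprintf("R%03d", 1:149)))
    res <- assign_single_parent(kid, cands, thr, cfg, freqs, panel)
    if (identical(res$parent, "TRUE-M")) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("the cascade is deterministic, keeps unknown-sex bears out of parent
           pools, and respects death-year compatibility", {
  set.seed(53)
  panel <- default_panel(10, 4)
  freqs <- random_freqs(panel, k = 6)
  mo <- draw_genos(1, freqs, panel, ids = "MOM")
  fa <- draw_genos(1, freqs, panel, ids = "DAD")
  kid <- mendel_child(mo, fa, panel, id = "KID")
  geno <- rbind(mo, fa, kid,
                draw_genos(6, freqs, panel, ids = sprintf("X%02d", 1:6)))
  ind <- data.frame(
    id = rownames(geno),
    sex = c("F", "M", "F", NA, "F", "F", "M", "M", "F"),
    mt = NA_character_, y = NA_character_,
    birth_year = c(2005L, 2004L, 2015L, rep(NA_integer_, 6)),
    death_year = NA_integer_,
    first_id_year = 2015L, last_id_year = 2020L,
    identified_window = TRUE, immigrant = FALSE,
    stringsAsFactors = FALSE)
  cfg <- assignment_config(error_rate = 0, n_simulation_cycles = 400,
                           n_candidates_per_offspring = 30)
  a1 <- run_cascade(ind, geno, panel, cfg, seed = 3)
  a2 <- run_cascade(ind, geno, panel, cfg, seed = 3)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  krow <- a1[a1$offspring_id == "KID", ]
  expect_identical(krow$mother_id, "MOM")
  expect_identical(krow$father_id, "DAD")
  # X01 has unknown sex: never appears as an assigned parent
  expect_false("X01" %in% c(a1$mother_id, a1$father_id))

  # a mother dead before the offspring's birth is filtered out
  ind2 <- ind
  ind2$death_year[ind2$id == "MOM"] <- 2010L
  a3 <- run_cascade(ind2, geno, panel, cfg, seed = 3)
  expect_false(identical(a3$mother_id[a3$offspring_id == "KID"], "MOM"))

  expect_error(run_cascade(rbind(ind, ind[1, ]), geno, panel, cfg, seed = 3),
               "duplicate")
})

test_that("accepted assignments never violate the mismatch tolerances", {
  p <- sim_params(years = 2012:2020, n0 = 40, seed = 61)
  tr <- simulate_population(p)
  ss <- simulate_sampling(tr)
  catg <- build_catalogue(ss$samples, ss$genotypes, tr$panel,
                          window = c(2019, 2020))
  cfg <- assignment_config(n_simulation_cycles = 500)
  asg <- run_cascade(catg$individuals, catg$genotypes, tr$panel, cfg, seed = 17)
  trio <- startsWith(asg$route, "trio")
  expect_true(all(asg$mismatches[asg$route == "trio-strict"] == 0L))
  expect_true(all(asg$mismatches[asg$route == "trio-relaxed"] <= 1L))
  expect_true(all(asg$mismatches[startsWith(asg$route, "dyad")] == 0L))
  # dyad routes set exactly one parent
  dy <- startsWith(asg$route, "dyad")
  expect_true(all(xor(!is.na(asg$mother_id[dy]), !is.na(asg$father_id[dy]))))
  # accepted mothers never predate the offspring
  ind <- catg$individuals
  for (r in which(!is.na(asg$mother_id))) {
    mi <- match(asg$mother_id[r], ind$id)
    ob <- ind$birth_year[match(asg$offspring_id[r], ind$id)]
    if (!is.na(ind$death_year[mi]) && !is.na(ob)) {
      expect_gte(ind$death_year[mi], ob)
    }
  }
})
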