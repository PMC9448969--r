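# Kinship likelihood ratios, sib-group clustering and hypothetical parents.

test_that("sib likelihoods match the closed-form kinship mixtures", {
  panel <- locus_panel("L1")
  f <- structure(list(L1 = c("1" = 0.5, "2" = 0.5)),
                 class = "allele_freq_table", absent = character(0))
  ll <- pairwise_sib_lr(g1(1, 1, panel = panel), g1(1, 1, panel = panel),
                        f, panel, e = 0)
  # unrelated: P(g1) P(g2) = 0.25 * 0.25
  expect_equal(exp(ll[["unrelated"]]), 0.0625)
  expect_gt(ll[["full_sib"]], ll[["unrelated"]])
  # disjoint alleles: full-sib likelihood reduces to the k0 term (1/4)
  f34 <- structure(list(L1 = c("1" = 0.25, "2" = 0.25, "3" = 0.25, "4" = 0.25)),
                   class = "allele_freq_table", absent = character(0))
  ll2 <- pairwise_sib_lr(g1(1, 2, panel = panel), g1(3, 4, panel = panel),
                         f34, panel, e = 0)
  expect_equal(ll2[["full_sib"]] - ll2[["unrelated"]], log(0.25))
})

test_that("true half-sib pairs outscore unrelated pairs in the majority", {
  set.seed(71)
  panel <- default_panel(21, 6)
  freqs <- random_freqs(panel, k = 6)
  pos <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    mo <- draw_genos(1, freqs, panel, ids = "m")
    f1 <- draw_genos(1, freqs, panel, ids = "f1")
    f2 <- draw_genos(1, freqs, panel, ids = "f2")
    k1 <- mendel_child(mo, f1, panel, id = "k1")
    k2 <- mendel_child(mo, f2, panel, id = "k2")
    ll <- pairwise_sib_lr(k1, k2, freqs, panel, e = 0)
    if (ll[["half_sib"]] > ll[["unrelated"]]) pos <- pos + 1L
  }
  expect_gt(pos / n_rep, 0.5)
})

test_that("maternal grouping respects mitochondrial haplotypes", {
  set.seed(73)
  panel <- default_panel(21, 6)
  freqs <- random_freqs(panel, k = 6)
  mo <- draw_genos(1, freqs, panel, ids = "m")
  f1 <- draw_genos(1, freqs, panel, ids = "f1")
  f2 <- draw_genos(1, freqs, panel, ids = "f2")
  k1 <- mendel_child(mo, f1, panel, id = "K1")
  k2 <- mendel_child(mo, f2, panel, id = "K2")
  geno <- rbind(k1, k2)
  base <- rbind(ind_row("K1", "F", mt = "H1", win = TRUE),
                ind_row("K2", "M", mt = "H1", win = TRUE))
  asg <- rbind(asg_row("K1"), asg_row("K2"))
  grp <- build_sib_groups(c("K1", "K2"), base, asg, geno, freqs, panel, e = 0)
  expect_length(grp$maternal, 1L)
  expect_setequal(grp$maternal[[1]], c("K1", "K2"))

  # different mt haplotypes can never share a hypothetical mother
  base2 <- base
  base2$mt <- c("H1", "H2")
  grp2 <- build_sib_groups(c("K1", "K2"), base2, asg, geno, freqs, panel, e = 0)
  expect_length(grp2$maternal, 2L)

  # no unassigned offspring: empty output
  asg3 <- rbind(asg_row("K1", mother = "X", father = "Y", route = "trio-strict"),
                asg_row("K2", mother = "X", father = "Y", route = "trio-strict"))
  grp3 <- build_sib_groups(c("K1", "K2"), base, asg3, geno, freqs, panel, e = 0)
  expect_length(grp3$maternal, 0L)
  expect_length(grp3$paternal, 0L)
})

test_that("paternal groups never mix known Y haplotypes", {
  set.seed(79)
  panel <- default_panel(21, 6)
  freqs <- random_freqs(panel, k = 6)
  fa <- draw_genos(1, freqs, panel, ids = "f")
  m1 <- draw_genos(1, freqs, panel, ids = "m1")
  m2 <- draw_genos(1, freqs, panel, ids = "m2")
  k1 <- mendel_child(fa, m1, panel, id = "S1")
  k2 <- mendel_child(fa, m2, panel, id = "S2")
  geno <- rbind(k1, k2)
  base <- rbind(ind_row("S1", "M", y = "Y1", win = TRUE),
                ind_row("S2", "M", y = "Y2", win = TRUE))
  asg <- rbind(asg_row("S1"), asg_row("S2"))
  grp <- build_sib_groups(c("S1", "S2"), base, asg, geno, freqs, panel, e = 0)
  expect_length(grp$paternal, 2L)
})

test_that("hypothetical parents carry anchors, haplotypes and offspring", {
  base <- rbind(ind_row("A", "F", birth = 2016, mt = "H3", win = TRUE),
                ind_row("B", "M", birth = 2018, mt = "H3", win = TRUE),
                ind_row("C", "F", birth = 2019, mt = "H3", win = TRUE))
  hp <- generate_hypothetical_parents(
    list(maternal = list(c("A", "B", "C")), paternal = list()), base)
  expect_equal(nrow(hp), 1L)
  expect_identical(hp$id, "HYP-F-001")
  expect_equal(hp$anchor_year, 2016L)
  expect_identical(hp$haplotype, "H3")
  expect_equal(hp$n_offspring, 3L)

  # singleton group
  hp2 <- generate_hypothetical_parents(
    list(maternal = list(), paternal = list("B")), base)
  expect_equal(nrow(hp2), 1L)
  expect_identical(hp2$sex, "M")
  expect_equal(hp2$n_offspring, 1L)

  # internally inconsistent haplotypes are an upstream bug, hence an error
  base_bad <- base
  base_bad$mt <- c("H3", "H4", "H3")
  expect_error(generate_hypothetical_parents(
    list(maternal = list(c("A", "B", "C")), paternal = list()), base_bad),
    "inconsistent")
})

test_that("an unsampled mother of four is mostly recovered as one group", {
  set.seed(83)
  panel <- default_panel(21, 6)
  majority_ok <- 0L
  n_rep <- 9L
  for (rep in seq_len(n_rep)) {
    freqs <- random_freqs(panel, k = 6)
    mo <- draw_genos(1, freqs, panel, ids = "unsampled-mom")
    sires <- draw_genos(4, freqs, panel, ids = sprintf("f%d", 1:4))
    kids <- do.call(rbind, lapply(1:4, function(i) {
      mendel_child(mo, sires[i, , drop = FALSE], panel, id = sprintf("K%d", i))
    }))
    noise <- draw_genos(4, freqs, panel, ids = sprintf("U%d", 1:4))
    geno <- rbind(kids, noise)
    base <- do.call(rbind, lapply(rownames(geno), function(id) {
      ind_row(id, "F", mt = if (startsWith(id, "K")) "HM" else paste0("HX", id),
              win = TRUE)
    }))
    asg <- do.call(rbind, lapply(rownames(geno), asg_row))
    grp <- build_sib_groups(rownames(geno), base, asg, geno, freqs, panel, e = 0)
    hp <- generate_hypothetical_parents(grp, base)
    covering <- hp[hp$sex == "F" &
                     vapply(hp$offspring_ids, function(v) {
                       sum(startsWith(v, "K")) >= 3
                     }, logical(1)), ]
    if (nrow(covering) >= 1L) majority_ok <- majority_ok + 1L
    # never more hypothetical mothers than maternally-unassigned offspring
    expect_lte(sum(hp$sex == "F"), nrow(geno))
  }
  expect_gt(majority_ok / n_rep, 0.5)
})
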