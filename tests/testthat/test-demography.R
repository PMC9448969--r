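# Demographic estimator: survival discounting, age estimates, liveness
# rules, bounds arithmetic, minimum census and density.

test_that("survival discounting compounds the annual rate", {
  cfg <- demography_config(reference_year = 2019)
  expect_equal(survival_weight(2017, "F", cfg), 0.94^2)
  expect_equal(round(survival_weight(2017, "F", cfg), 2), 0.88)
  expect_equal(survival_weight(2019, "M", cfg), 1.0)
  expect_equal(survival_weight(2018, "M", cfg), 0.89)
  expect_error(survival_weight(2020, "F", cfg), "after the reference year")
})

test_that("hypothetical-parent ages add the generation interval", {
  cfg <- demography_config(reference_year = 2019)
  expect_equal(hypothetical_parent_age(2012, cfg), 14.3)
  expect_equal(hypothetical_parent_age(2019, cfg), 7.3)
  expect_equal(hypothetical_parent_age(1996, cfg), 30.3)
})

test_that("breeder classification needs window identification and offspring", {
  ind <- rbind(ind_row("F1", "F", win = TRUE),
               ind_row("M1", "M", win = TRUE),
               ind_row("F2", "F", win = FALSE),
               ind_row("K1", "F", win = TRUE))
  asg <- rbind(asg_row("K1", mother = "F1", route = "dyad-mother"),
               asg_row("F1"), asg_row("M1"), asg_row("F2"))
  b <- classify_breeders(asg, ind)
  expect_identical(b$F, "F1")   # identified + offspring
  expect_length(b$M, 0)         # identified, no offspring
})

test_that("adult evidence rules follow identification and parent-death bounds", {
  cfg <- demography_config(reference_year = 2019)
  ind <- rbind(
    ind_row("A", "F", first = 2014, last = 2019, win = TRUE),   # >=5 years known
    ind_row("B", "M", first = 2018, last = 2019, win = TRUE),   # no evidence
    ind_row("C", "F", first = 2019, last = 2019, win = TRUE),   # via dead father
    ind_row("D", "M", first = 2019, last = 2019, win = TRUE, birth = 2012),
    ind_row("PA", "M", first = 2000, last = 2014, death = 2014, win = FALSE))
  asg <- rbind(asg_row("A"), asg_row("B"),
               asg_row("C", father = "PA", route = "dyad-father"),
               asg_row("D"), asg_row("PA"))
  ad <- classify_adults_no_record(ind, asg, cfg)
  # father dead 2014 => born <= 2015 => >= 4 years old in 2019
  expect_setequal(ad$F, c("A", "C"))
  expect_setequal(ad$M, "D")
})

test_that("breeding bounds reproduce the aggregation arithmetic", {
  b <- breeding_bounds_from_counts(10, 1, 1, 2.6, 3)
  expect_equal(unname(b), c(12, 12 + round(5.6)))
  # zero additions collapse the interval onto the confirmed count
  b0 <- breeding_bounds_from_counts(7, 0, 0, 0, 0)
  expect_equal(unname(b0), c(7, 7))
  # fractional weights are summed before rounding
  b2 <- breeding_bounds_from_counts(0, 0, 0, 0.4 + 0.4, 0)
  expect_equal(unname(b2["max"]), 1)  # 0.8 rounds to 1; per-term rounding would give 0
})

test_that("adult bounds shift by the no-record adults", {
  bb <- matrix(c(10, 20, 5, 8), 2, 2, dimnames = list(c("min", "max"), c("F", "M")))
  ad <- adult_population_bounds(bb, list(F = c("a", "b"), M = character(0)))
  expect_equal(unname(ad[, "F"]), c(12, 22))
  expect_equal(unname(ad[, "M"]), c(5, 8))
})

test_that("liveness rules label minimum-counted, senescent and over-deep parents", {
  cfg <- demography_config(reference_year = 2019)
  ind <- rbind(
    ind_row("K18", "F", birth = 2018, first = 2019, last = 2019, win = TRUE,
            ref = TRUE),
    ind_row("K20", "M", birth = 2020, first = 2020, last = 2020, win = TRUE,
            refp1 = TRUE),
    ind_row("EX1", "F", first = 2008, last = 2017, win = FALSE),
    ind_row("OLD", "F", first = 1990, last = 2010, win = FALSE),
    # living matriline for the generation-limit rule
    ind_row("G1", "F", birth = 1999, first = 2019, last = 2019, win = TRUE, ref = TRUE),
    ind_row("G2", "F", birth = 2006, first = 2019, last = 2019, win = TRUE, ref = TRUE),
    ind_row("G3", "F", birth = 2013, first = 2019, last = 2019, win = TRUE, ref = TRUE),
    ind_row("G4", "F", birth = 2019, first = 2019, last = 2019, win = TRUE, ref = TRUE))
  asg <- rbind(
    asg_row("K18", mother = "EX1", route = "dyad-mother"),
    asg_row("K20", father = "HYP-M-001", route = "sibship"),
    asg_row("G1", mother = "HYP-F-001", route = "sibship"),
    asg_row("G2", mother = "G1", route = "dyad-mother"),
    asg_row("G3", mother = "G2", route = "dyad-mother"),
    asg_row("G4", mother = "G3", route = "dyad-mother"),
    asg_row("EX1"), asg_row("OLD"))
  hyp <- rbind(hyp_row("HYP-M-001", "M", "K20", 2020),
               hyp_row("HYP-F-001", "F", "G1", 1999))
  ped <- fake_pedigree(asg, hyp)
  lv <- apply_liveness_rules(ind, ped, cfg)

  # mother of a 2018 cub that survived to age 1 in 2019: alive until separation
  expect_identical(lv$status[lv$id == "EX1"], "counted-minimum")
  # father of a cub of the year sampled 2020: mated in 2019
  expect_identical(lv$status[lv$id == "HYP-M-001"], "counted-minimum")
  # hypothetical mother atop four living matrilineal generations:
  # she would be a great-great-grandmother
  expect_identical(lv$status[lv$id == "HYP-F-001"], "dead-generation-limit")

  # monitoring override wins over 'alive'
  lv2 <- apply_liveness_rules(ind, ped, cfg, overrides = "EX1")
  expect_identical(lv2$status[lv2$id == "EX1"], "counted-minimum")  # cub evidence is stronger
  asg2 <- asg
  asg2$mother_id[asg2$offspring_id == "K18"] <- NA
  asg2$mother_id[asg2$offspring_id == "G3"] <- "EX1"
  lv3 <- apply_liveness_rules(ind, fake_pedigree(asg2, hyp), cfg,
                              overrides = "EX1")
  expect_identical(lv3$status[lv3$id == "EX1"], "dead-monitoring")
})

test_that("senescence uses the real-valued pedigree age bound", {
  cfg <- demography_config(reference_year = 2019)
  # hypothetical mother anchored 1996: age 23 + 7.3 = 30.3 >= 30 -> dead
  ind <- rbind(ind_row("X", "F", birth = 1996, first = 2019, last = 2019,
                       win = TRUE, ref = TRUE))
  asg <- rbind(asg_row("X", mother = "HYP-F-009", route = "sibship"))
  ped <- fake_pedigree(asg, hyp_row("HYP-F-009", "F", "X", 1996))
  lv <- apply_liveness_rules(ind, ped, cfg)
  expect_identical(lv$status[lv$id == "HYP-F-009"], "dead-senescence")
  expect_equal(lv$age_estimate[lv$id == "HYP-F-009"], 30.3)
})

test_that("breeders_max is monotone in alive hypothetical parents", {
  confirmed <- list(F = c("a", "b"), M = "c")
  lv <- data.frame(id = c("h1", "e1"), sex = c("F", "F"),
                   type = c("hypothetical", "existing"),
                   status = c("alive", "alive"), weight = c(1, 0.83),
                   age_estimate = NA_real_, stringsAsFactors = FALSE)
  b1 <- breeding_population_bounds(confirmed, lv)
  lv2 <- rbind(lv, data.frame(id = "h2", sex = "F", type = "hypothetical",
                              status = "alive", weight = 1,
                              age_estimate = NA_real_))
  b2 <- breeding_population_bounds(confirmed, lv2)
  expect_gte(b2["max", "F"], b1["max", "F"])
  # removing a liveness exclusion (dead -> alive) never decreases the max
  lv3 <- rbind(lv, data.frame(id = "h3", sex = "F", type = "hypothetical",
                              status = "dead-senescence", weight = 0,
                              age_estimate = 31))
  b3 <- breeding_population_bounds(confirmed, lv3)
  lv3$status[lv3$id == "h3"] <- "alive"
  lv3$weight[lv3$id == "h3"] <- 1
  b4 <- breeding_population_bounds(confirmed, lv3)
  expect_gte(b4["max", "F"], b3["max", "F"])
})

test_that("the minimum census includes the right categories", {
  cfg <- demography_config(reference_year = 2019)
  ind <- rbind(
    ind_row("A", "F", birth = 2010, first = 2019, last = 2019, win = TRUE, ref = TRUE),
    # died during the reference year: still counted
    ind_row("B", "M", birth = 2014, death = 2019, first = 2019, last = 2019,
            win = TRUE, ref = TRUE),
    # 2020-only with known birth <= 2019: counted, age class 1
    ind_row("C", "F", birth = 2018, first = 2020, last = 2020, win = TRUE,
            refp1 = TRUE),
    # 2020-only, no age evidence: possible cub of the year, excluded
    ind_row("D", "M", first = 2020, last = 2020, win = TRUE, refp1 = TRUE),
    # identified earlier and in 2020 only: min age >= 4 -> adult class
    ind_row("E", "F", first = 2012, last = 2020, win = TRUE, refp1 = TRUE))
  asg <- do.call(rbind, lapply(ind$id, asg_row))
  ped <- fake_pedigree(asg)
  lv <- apply_liveness_rules(ind, ped, cfg)
  mp <- minimum_population(ind, ped, lv, cfg)
  expect_setequal(mp$members$id, c("A", "B", "C", "E"))
  expect_equal(mp$total, 4)
  expect_equal(unname(mp$by_sex["F"]), 3)
  expect_equal(mp$table["1", "F"], 1L)     # C is one year old in 2019
  expect_equal(mp$table[">=4", "F"], 2L)   # A exact age, E by min-age bound
})

test_that("density scales to 100 km2", {
  expect_equal(density_per_100km2(0, 1760), 0)
  expect_equal(round(density_per_100km2(52, 640), 1), 8.1)
})
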