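# Demographic estimation from a reconstructed pedigree: breeder/adult
# classification, liveness rules for unresampled and hypothetical parents
# (survival discounting, reproductive senescence, coexisting-generation
# limits, monitoring overrides), breeding/adult population bounds, the
# minimum census size with an age-class breakdown, and density.

#' Demographic estimator configuration
#'
#' Parameters of the pedigree-based population estimator. Defaults are the
#' study conditions for a high-density brown bear population assessed as of
#' 2019: adult age 4+, sex-specific annual survival 0.94 (F) / 0.89 (M)
#' used for discounting unresampled parents, reproductive senescence at 30
#' (F) / 28 (M) years, a 7.3-year mother-offspring generation interval used
#' to lower-bound hypothetical parents' ages, at most 4 matrilineal and 3
#' patrilineal generations coexisting, and study/forest areas of 1760 and
#' 1378 km2 for density.
#'
#' @param reference_year Census year (first year of the intensive survey).
#' @param adult_age_min Minimum adult age in years.
#' @param survival_f,survival_m Annual adult survival rates by sex.
#' @param senescence_age_f,senescence_age_m Ages at which parents are
#'   treated as reproductively dead.
#' @param generation_interval Years added to the oldest-offspring birth year
#'   to lower-bound a parent's age.
#' @param max_matrilineal_generations,max_patrilineal_generations Maximum
#'   numbers of coexisting generations.
#' @param study_area_km2,forest_area_km2 Area bases for density.
#' @return A list of class `demography_config`.
#' @export
demography_config <- function(reference_year = 2019L,
                              adult_age_min = 4L,
                              survival_f = 0.94,
                              survival_m = 0.89,
                              senescence_age_f = 30,
                              senescence_age_m = 28,
                              generation_interval = 7.3,
                              max_matrilineal_generations = 4L,
                              max_patrilineal_generations = 3L,
                              study_area_km2 = 1760,
                              forest_area_km2 = 1378) {
  stopifnot(senescence_age_f > adult_age_min, senescence_age_m > adult_age_min,
            survival_f > 0, survival_f <= 1, survival_m > 0, survival_m <= 1)
  structure(list(reference_year = as.integer(reference_year),
                 adult_age_min = as.integer(adult_age_min),
                 survival_f = survival_f, survival_m = survival_m,
                 senescence_age_f = senescence_age_f,
                 senescence_age_m = senescence_age_m,
                 generation_interval = generation_interval,
                 max_matrilineal_generations = as.integer(max_matrilineal_generations),
                 max_patrilineal_generations = as.integer(max_patrilineal_generations),
                 study_area_km2 = study_area_km2,
                 forest_area_km2 = forest_area_km2),
            class = "demography_config")
}

#' Survival-discount weight of an unresampled parent
#'
#' A parent last identified before the reference year is weighted by
#' \eqn{s^{(\mathrm{ref} - \mathrm{last})}} with the sex-specific annual
#' survival rate, e.g. a female last seen two years before the census
#' counts as 0.94 x 0.94 = 0.8836 of an individual. The raw value is
#' returned; round only at presentation.
#'
#' @param last_id_year Year of last identification.
#' @param sex `"F"` or `"M"`.
#' @param config A [demography_config()].
#' @return Numeric weight in (0, 1].
#' @export
survival_weight <- function(last_id_year, sex, config = demography_config()) {
  if (any(last_id_year > config$reference_year)) {
    stop("last_id_year is after the reference year")
  }
  s <- ifelse(sex == "F", config$survival_f, config$survival_m)
  s^(config$reference_year - last_id_year)
}

#' Lower-bound age estimate of a hypothetical parent
#'
#' The parent must have been at least `generation_interval` years old at
#' the birth of its oldest offspring, so its age at the reference year is
#' at least `(reference_year - anchor_year) + generation_interval`.
#'
#' @param anchor_year Birth year of the oldest offspring. May exceed the
#'   reference year by one (a parent of a cub born just after the census),
#'   in which case the age bound is correspondingly smaller.
#' @param config A [demography_config()].
#' @return Numeric age (real-valued).
#' @export
hypothetical_parent_age <- function(anchor_year, config = demography_config()) {
  if (any(anchor_year > config$reference_year + 1L)) {
    stop("anchor year is more than one year after the reference year")
  }
  (config$reference_year - anchor_year) + config$generation_interval
}

#' Confirmed breeders by sex
#'
#' Bears identified in the intensive-survey window with at least one
#' offspring in the pedigree (real links only; hypothetical parents are by
#' construction not identified individuals).
#'
#' @param assignments Parentage table (`offspring_id`, `mother_id`,
#'   `father_id`).
#' @param individuals Individual table with `id`, `sex` and logical
#'   `identified_window`.
#' @return List with character vectors `F` and `M`.
#' @export
classify_breeders <- function(assignments, individuals) {
  parents <- c(assignments$mother_id, assignments$father_id)
  parents <- unique(parents[!is.na(parents)])
  inw <- individuals$id[individuals$identified_window %in% TRUE]
  conf <- intersect(parents, inw)
  sex <- individuals$sex[match(conf, individuals$id)]
  list(F = conf[sex %in% "F"], M = conf[sex %in% "M"])
}

# Earliest possible birth year implied by a dead parent: a mother must be
# alive in the offspring's birth year (born <= mother's death year), a
# father only at conception (born <= father's death year + 1).
parent_death_birth_bound <- function(ids, assignments, individuals) {
  bound <- rep(NA_integer_, length(ids))
  rows <- match(ids, assignments$offspring_id)
  for (k in seq_along(ids)) {
    r <- rows[k]
    if (is.na(r)) next
    b <- NA_integer_
    m <- assignments$mother_id[r]
    if (!is.na(m)) {
      md <- individuals$death_year[match(m, individuals$id)]
      if (length(md) == 1L && !is.na(md)) b <- min(b, md, na.rm = TRUE)
    }
    f <- assignments$father_id[r]
    if (!is.na(f)) {
      fd <- individuals$death_year[match(f, individuals$id)]
      if (length(fd) == 1L && !is.na(fd)) b <- min(b, fd + 1L, na.rm = TRUE)
    }
    bound[k] <- b
  }
  bound
}

#' Additional adults without a breeding record
#'
#' Bears identified in the survey window, not classified as breeders, with
#' any evidence implying age >= `adult_age_min` at the reference year: a
#' known birth year (monitoring or cementum ageing), a first identification
#' at least `adult_age_min` years before the reference year, or a parent
#' death year that bounds their birth year sufficiently far back.
#'
#' @inheritParams classify_breeders
#' @param config A [demography_config()].
#' @return List with character vectors `F` and `M`.
#' @export
classify_adults_no_record <- function(individuals, assignments,
                                      config = demography_config()) {
  ref <- config$reference_year
  amin <- config$adult_age_min
  breeders <- classify_breeders(assignments, individuals)
  cand <- individuals[individuals$identified_window %in% TRUE &
                        !(individuals$id %in% c(breeders$F, breeders$M)), ]
  if (nrow(cand) == 0L) return(list(F = character(0), M = character(0)))
  by_birth <- !is.na(cand$birth_year) & (ref - cand$birth_year) >= amin
  by_first <- !is.na(cand$first_id_year) & cand$first_id_year <= ref - amin
  bound <- parent_death_birth_bound(cand$id, assignments, individuals)
  by_parent <- !is.na(bound) & (ref - bound) >= amin
  keep <- by_birth | by_first | by_parent
  list(F = cand$id[keep & cand$sex %in% "F"],
       M = cand$id[keep & cand$sex %in% "M"])
}

# Maximum depth of a chain of descendants, all present at the reference
# year, below `id` following the given parent-slot links.
living_descendant_depth <- function(id, assignments, living_ids, slot) {
  kids <- assignments$offspring_id[!is.na(assignments[[slot]]) &
                                     assignments[[slot]] == id]
  kids <- intersect(kids, living_ids)
  if (length(kids) == 0L) return(0L)
  1L + max(vapply(kids, living_descendant_depth, integer(1),
                  assignments = assignments, living_ids = living_ids,
                  slot = slot))
}

#' Classify liveness of unresampled and hypothetical parents
#'
#' Every parent of a survey-window offspring that was not itself identified
#' in the window is labelled:
#' \describe{
#'   \item{counted-minimum}{demonstrably alive at the reference year because
#'     it produced a cub in the three years around it: a mother of a cub
#'     born in the reference year or the year after, or of a cub born the
#'     year before that survived to age 1; a father of a cub born the year
#'     after the reference year (mated in the reference year).}
#'   \item{dead-observed}{known dead before the reference year.}
#'   \item{dead-monitoring}{on the explicit override list (e.g. mothers of
#'     resident adult females unobserved for many years).}
#'   \item{dead-senescence}{estimated age at the reference year at or above
#'     the sex-specific senescence threshold. For real parents the age
#'     estimate is the best available lower bound (known birth year, first
#'     identification, or oldest-offspring birth year plus the generation
#'     interval); for hypothetical parents it is
#'     [hypothetical_parent_age()].}
#'   \item{dead-generation-limit}{a hypothetical parent whose chain of
#'     living same-line descendants would make it exceed the maximum number
#'     of coexisting matrilineal (4) or patrilineal (3) generations.}
#'   \item{alive}{otherwise; real parents carry a [survival_weight()] for
#'     the maximum bound, hypothetical parents weight 1.}
#' }
#'
#' @param individuals Individual table.
#' @param pedigree A [reconstruct_pedigree()] result, or a list with
#'   `assignments` and `hypothetical`.
#' @param config A [demography_config()].
#' @param overrides Character vector of parent ids known dead from
#'   monitoring.
#' @return Data frame (`id`, `sex`, `type`, `status`, `weight`,
#'   `age_estimate`) -- the audit ledger of the maximum bound.
#' @export
apply_liveness_rules <- function(individuals, pedigree,
                                 config = demography_config(),
                                 overrides = character(0)) {
  ref <- config$reference_year
  asg <- pedigree$assignments
  hyp <- pedigree$hypothetical
  inw <- individuals$identified_window %in% TRUE
  window_ids <- individuals$id[inw]

  off_in_window <- asg$offspring_id %in% window_ids
  parents <- unique(c(asg$mother_id[off_in_window], asg$father_id[off_in_window]))
  parents <- parents[!is.na(parents)]
  real <- parents[parents %in% individuals$id]
  real <- real[!(real %in% window_ids)]  # existing but unresampled in window
  hyp_ids <- parents[startsWith(parents, "HYP-")]

  living_ids <- individuals$id[inw &
                                 (is.na(individuals$death_year) |
                                    individuals$death_year >= ref)]

  counted_minimum <- function(pid, sex) {
    kids <- asg$offspring_id[(!is.na(asg$mother_id) & asg$mother_id == pid & sex == "F") |
                               (!is.na(asg$father_id) & asg$father_id == pid & sex == "M")]
    kb <- individuals$birth_year[match(kids, individuals$id)]
    kl <- individuals$last_id_year[match(kids, individuals$id)]
    kd <- individuals$death_year[match(kids, individuals$id)]
    if (sex == "F") {
      born_ref <- any(!is.na(kb) & (kb == ref | kb == ref + 1L))
      prev_survived <- any(!is.na(kb) & kb == ref - 1L &
                             ((!is.na(kl) & kl >= ref) | (!is.na(kd) & kd >= ref)))
      born_ref || prev_survived
    } else {
      any(!is.na(kb) & kb == ref + 1L)
    }
  }

  rows <- list()
  for (pid in real) {
    i <- match(pid, individuals$id)
    sex <- individuals$sex[i]
    kids <- asg$offspring_id[(!is.na(asg$mother_id) & asg$mother_id == pid) |
                               (!is.na(asg$father_id) & asg$father_id == pid)]
    kb <- individuals$birth_year[match(kids, individuals$id)]
    # best lower bound on age at the reference year
    age_est <- suppressWarnings(max(
      if (!is.na(individuals$birth_year[i])) ref - individuals$birth_year[i] else -Inf,
      if (!is.na(individuals$first_id_year[i])) ref - individuals$first_id_year[i] else -Inf,
      if (any(!is.na(kb))) (ref - min(kb, na.rm = TRUE)) + config$generation_interval else -Inf))
    sen <- if (sex %in% "F") config$senescence_age_f else config$senescence_age_m
    status <-
      if (counted_minimum(pid, sex)) "counted-minimum"
      else if (!is.na(individuals$death_year[i]) && individuals$death_year[i] < ref) "dead-observed"
      else if (pid %in% overrides) "dead-monitoring"
      else if (is.finite(age_est) && age_est >= sen) "dead-senescence"
      else "alive"
    w <- switch(status,
                "alive" = survival_weight(min(individuals$last_id_year[i], ref), sex, config),
                "counted-minimum" = 1,
                0)
    rows[[length(rows) + 1L]] <-
      data.frame(id = pid, sex = sex, type = "existing", status = status,
                 weight = w,
                 age_estimate = if (is.finite(age_est)) age_est else NA_real_,
                 stringsAsFactors = FALSE)
  }

  for (k in seq_len(nrow(hyp))) {
    pid <- hyp$id[k]
    if (!(pid %in% hyp_ids)) next
    sex <- hyp$sex[k]
    anchor <- hyp$anchor_year[k]
    age_est <- if (!is.na(anchor)) hypothetical_parent_age(anchor, config) else NA_real_
    sen <- if (sex == "F") config$senescence_age_f else config$senescence_age_m
    slot <- if (sex == "F") "mother_id" else "father_id"
    depth <- living_descendant_depth(pid, asg, living_ids, slot)
    max_gen <- if (sex == "F") config$max_matrilineal_generations else config$max_patrilineal_generations
    status <-
      if (counted_minimum(pid, sex)) "counted-minimum"
      else if (pid %in% overrides) "dead-monitoring"
      else if (!is.na(age_est) && age_est >= sen) "dead-senescence"
      else if (depth >= max_gen) "dead-generation-limit"
      else "alive"
    w <- switch(status, "alive" = 1, "counted-minimum" = 1, 0)
    rows[[length(rows) + 1L]] <-
      data.frame(id = pid, sex = sex, type = "hypothetical", status = status,
                 weight = w, age_estimate = age_est, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(0), sex = character(0),
                      type = character(0), status = character(0),
                      weight = numeric(0), age_estimate = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Breeding-population bounds from category counts
#'
#' The aggregation rule of the estimator: the minimum number of breeders is
#' the confirmed breeders plus the parents counted as demonstrably alive
#' (minimum-counted existing and hypothetical parents); the maximum adds
#' the survival-discounted weights of the alive existing unresampled
#' parents and the alive hypothetical parents, with the added total rounded
#' to the nearest integer after summation.
#'
#' @param n_confirmed Number of confirmed breeders.
#' @param n_min_existing,n_min_hyp Minimum-counted existing / hypothetical
#'   parents.
#' @param w_max_existing Summed survival weights of alive existing
#'   unresampled parents (fractional).
#' @param n_max_hyp Number of alive hypothetical parents.
#' @return Named numeric vector `c(min, max)`.
#' @examples
#' breeding_bounds_from_counts(125, 1, 2, 9.3, 36)  # 128, 173
#' @export
breeding_bounds_from_counts <- function(n_confirmed, n_min_existing, n_min_hyp,
                                        w_max_existing, n_max_hyp) {
  lo <- n_confirmed + n_min_existing + n_min_hyp
  hi <- lo + round(w_max_existing + n_max_hyp)
  c(min = lo, max = hi)
}

#' Breeding-population bounds from a liveness ledger
#'
#' @param confirmed A [classify_breeders()] result.
#' @param liveness An [apply_liveness_rules()] ledger.
#' @param config A [demography_config()].
#' @return Matrix with rows `min`, `max` and columns `F`, `M`.
#' @export
breeding_population_bounds <- function(confirmed, liveness,
                                       config = demography_config()) {
  out <- matrix(0, 2, 2, dimnames = list(c("min", "max"), c("F", "M")))
  for (sx in c("F", "M")) {
    lv <- liveness[liveness$sex == sx, , drop = FALSE]
    b <- breeding_bounds_from_counts(
      n_confirmed = length(confirmed[[sx]]),
      n_min_existing = sum(lv$status == "counted-minimum" & lv$type == "existing"),
      n_min_hyp = sum(lv$status == "counted-minimum" & lv$type == "hypothetical"),
      w_max_existing = sum(lv$weight[lv$status == "alive" & lv$type == "existing"]),
      n_max_hyp = sum(lv$status == "alive" & lv$type == "hypothetical"))
    out[, sx] <- b
  }
  out
}

#' Adult-population bounds
#'
#' Both breeding bounds shifted by the number of additional bears with
#' evidence of adult age but no breeding record.
#'
#' @param breeding_bounds Matrix from [breeding_population_bounds()].
#' @param adults_no_record A [classify_adults_no_record()] result (or named
#'   numeric vector of counts).
#' @return Matrix with rows `min`, `max` and columns `F`, `M`.
#' @export
adult_population_bounds <- function(breeding_bounds, adults_no_record) {
  n <- if (is.list(adults_no_record)) {
    c(F = length(adults_no_record$F), M = length(adults_no_record$M))
  } else {
    adults_no_record
  }
  breeding_bounds + rbind(n, n)
}

age_class_of <- function(age) {
  ifelse(is.na(age), "unknown",
         ifelse(age >= 4, ">=4",
                ifelse(age >= 2, "2-3", ifelse(age >= 1, "1", "0"))))
}

#' Minimum population size at the reference year
#'
#' Deduplicated union of three categories: (1) bears identified in the
#' reference year, including bears that died in it; (2) bears not
#' identified during the survey window whose presence at the reference year
#' is inferred from the pedigree (the minimum-counted existing and
#' hypothetical parents); (3) bears identified only in the year after the
#' reference year, with evidence of being at least one year old then (known
#' birth year, earlier identification, or a parent-death bound) -- bears
#' that could be cubs of that following year are excluded. Each member is
#' placed in an age class (>=4, 2-3, 1, 0, unknown) at the reference year;
#' a known age gives the exact class, a lower bound of 4+ gives the adult
#' class, anything less is unknown. Inferred parents are breeders and enter
#' the adult class.
#'
#' @param individuals Individual table with logicals `identified_ref` and
#'   `identified_refp1` (identified in the reference year / the year
#'   after).
#' @param pedigree A [reconstruct_pedigree()] result.
#' @param liveness An [apply_liveness_rules()] ledger.
#' @param config A [demography_config()].
#' @return List with `total`, `by_sex`, `table` (age class x sex counts)
#'   and `members` (audit data frame).
#' @export
minimum_population <- function(individuals, pedigree, liveness,
                               config = demography_config()) {
  ref <- config$reference_year
  asg <- pedigree$assignments
  ind <- individuals

  in_ref <- ind$identified_ref %in% TRUE
  in_refp1 <- ind$identified_refp1 %in% TRUE

  # category 3: identified only the year after, demonstrably >= 1 year old
  bound <- parent_death_birth_bound(ind$id, asg, ind)
  born_by_ref <- (!is.na(ind$birth_year) & ind$birth_year <= ref) |
    (!is.na(ind$first_id_year) & ind$first_id_year <= ref) |
    (!is.na(bound) & bound <= ref)
  cat3 <- !in_ref & in_refp1 & born_by_ref

  keep <- in_ref | cat3
  members <- data.frame(id = ind$id[keep], sex = ind$sex[keep],
                        stringsAsFactors = FALSE)
  age <- ifelse(!is.na(ind$birth_year[keep]), ref - ind$birth_year[keep], NA_real_)
  min_age <- ifelse(!is.na(ind$first_id_year[keep]),
                    ref - ind$first_id_year[keep], NA_real_)
  cls <- age_class_of(age)
  cls[is.na(age) & !is.na(min_age) & min_age >= config$adult_age_min] <- ">=4"
  members$age_class <- cls
  members$category <- ifelse(in_ref[keep], "identified-ref", "identified-next-year")

  # category 2: pedigree-inferred presence (minimum-counted parents)
  inferred <- liveness[liveness$status == "counted-minimum", , drop = FALSE]
  inferred <- inferred[!(inferred$id %in% members$id), , drop = FALSE]
  if (nrow(inferred) > 0L) {
    members <- rbind(members,
                     data.frame(id = inferred$id, sex = inferred$sex,
                                age_class = ">=4",
                                category = "pedigree-inferred",
                                stringsAsFactors = FALSE))
  }
  members <- members[!duplicated(members$id), ]

  classes <- c(">=4", "2-3", "1", "0", "unknown")
  tab <- matrix(0L, length(classes), 2,
                dimnames = list(classes, c("F", "M")))
  for (cl in classes) {
    for (sx in c("F", "M")) {
      tab[cl, sx] <- sum(members$age_class == cl & members$sex %in% sx)
    }
  }
  list(total = nrow(members),
       by_sex = c(F = sum(members$sex %in% "F"), M = sum(members$sex %in% "M")),
       table = tab, members = members)
}

#' Density per 100 km2
#'
#' @param count Number of bears.
#' @param area_km2 Area in km2.
#' @return Bears per 100 km2 (raw; round to 1 decimal at presentation).
#' @export
density_per_100km2 <- function(count, area_km2) {
  count / area_km2 * 100
}

#' Estimate breeding, adult and minimum population sizes from a pedigree
#'
#' The top-level estimator: classifies confirmed breeders and additional
#' adults among the survey-window bears, applies the liveness rules to
#' unresampled and hypothetical parents, and assembles breeding bounds,
#' adult bounds, the minimum census size and densities.
#'
#' @param individuals Individual table (see [run_cascade()]), additionally
#'   with logicals `identified_window`, `identified_ref`,
#'   `identified_refp1`.
#' @param pedigree A [reconstruct_pedigree()] result.
#' @param config A [demography_config()].
#' @param overrides Character ids of parents known dead from monitoring.
#' @return An object of class `bear_popest`.
#' @export
estimate_population <- function(individuals, pedigree,
                                config = demography_config(),
                                overrides = character(0)) {
  confirmed <- classify_breeders(pedigree$assignments, individuals)
  liveness <- apply_liveness_rules(individuals, pedigree, config, overrides)
  breeding <- breeding_population_bounds(confirmed, liveness, config)
  adults_extra <- classify_adults_no_record(individuals, pedigree$assignments, config)
  adults <- adult_population_bounds(breeding, adults_extra)
  minpop <- minimum_population(individuals, pedigree, liveness, config)
  dens <- c(study_area = density_per_100km2(minpop$total, config$study_area_km2),
            forest_area = density_per_100km2(minpop$total, config$forest_area_km2))
  structure(list(breeding = breeding, adults = adults,
                 confirmed_breeders = confirmed,
                 adults_no_record = adults_extra,
                 liveness = liveness, minimum_population = minpop,
                 density = dens, config = config),
            class = "bear_popest")
}

#' Assemble a population estimate from printed category counts
#'
#' Bookkeeping constructor: builds the same estimate object directly from
#' category counts (confirmed breeders, minimum/maximum parent additions,
#' additional adults, and an optional age-class table for the minimum
#' population), for checking the aggregation arithmetic against published
#' tables.
#'
#' @param confirmed Named vector `c(F=, M=)` of confirmed breeders.
#' @param min_existing,min_hyp Named vectors of minimum-counted parents.
#' @param max_existing_weighted Named vector of summed survival weights.
#' @param max_hyp Named vector of alive hypothetical parents.
#' @param adults_no_record Named vector of additional adults.
#' @param min_pop_table Optional age-class x sex matrix (rows `>=4`, `2-3`,
#'   `1`, `0`, `unknown`; columns `F`, `M`).
#' @param config A [demography_config()].
#' @return An object of class `bear_popest` (without per-individual audit).
#' @export
popest_from_counts <- function(confirmed, min_existing, min_hyp,
                               max_existing_weighted, max_hyp,
                               adults_no_record,
                               min_pop_table = NULL,
                               config = demography_config()) {
  breeding <- matrix(0, 2, 2, dimnames = list(c("min", "max"), c("F", "M")))
  for (sx in c("F", "M")) {
    breeding[, sx] <- breeding_bounds_from_counts(
      confirmed[[sx]], min_existing[[sx]], min_hyp[[sx]],
      max_existing_weighted[[sx]], max_hyp[[sx]])
  }
  adults <- adult_population_bounds(breeding, adults_no_record)
  minpop <- NULL
  dens <- NULL
  if (!is.null(min_pop_table)) {
    by_sex <- colSums(min_pop_table)
    minpop <- list(total = sum(min_pop_table), by_sex = by_sex,
                   table = min_pop_table, members = NULL)
    dens <- c(study_area = density_per_100km2(minpop$total, config$study_area_km2),
              forest_area = density_per_100km2(minpop$total, config$forest_area_km2))
  }
  structure(list(breeding = breeding, adults = adults,
                 confirmed_breeders = NULL, adults_no_record = adults_no_record,
                 liveness = NULL, minimum_population = minpop,
                 density = dens, config = config),
            class = "bear_popest")
}

#' @export
print.bear_popest <- function(x, ...) {
  fmt <- function(m) sprintf("%d-%d (F), %d-%d (M)",
                             m["min", "F"], m["max", "F"],
                             m["min", "M"], m["max", "M"])
  cat("Pedigree-based population estimate (reference year ",
      x$config$reference_year, ")\n", sep = "")
  cat("  Breeding population size: ", fmt(x$breeding), "\n", sep = "")
  cat("  Adult (>=", x$config$adult_age_min, " years) population size: ",
      fmt(x$adults), "\n", sep = "")
  if (!is.null(x$minimum_population)) {
    mp <- x$minimum_population
    cat("  Minimum population size: ", mp$total,
        " (", mp$by_sex[["F"]], " F / ", mp$by_sex[["M"]], " M)\n", sep = "")
    cat("  Density: ", round(x$density[["study_area"]], 1), " / ",
        round(x$density[["forest_area"]], 1),
        " bears per 100 km2 (study / forest area)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.bear_popest <- function(object, ...) {
  print(object)
  if (!is.null(object$minimum_population)) {
    cat("\nMinimum population by age class:\n")
    print(object$minimum_population$table)
  }
  if (!is.null(object$liveness) && nrow(object$liveness)) {
    cat("\nParent liveness ledger:\n")
    print(table(object$liveness$type, object$liveness$status))
  }
  invisible(object)
}
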