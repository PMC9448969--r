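# Individual-based population simulator with known ground truth: overlapping
# generations, polygamous mating with an age-weighted male success curve,
# sex-specific mortality, Mendelian inheritance at a multilocus
# microsatellite panel, maternally inherited mitochondrial and paternally
# inherited Y haplotypes, occasional immigrant males carrying a foreign
# mitochondrial haplotype, and multi-year heterogeneous sampling
# (hair / feces / other / dead recovery) with replicated genotyping.

#' Simulation parameters
#'
#' Defaults emulate the study system: a population of a few hundred bears
#' followed over 1998-2020 with opportunistic monitoring and two final
#' years of intensive sampling; 21 loci averaging ~5.8 alleles; seven
#' mitochondrial and seven Y haplotypes; adult survival 0.94 (F) / 0.89 (M);
#' females first reproduce around age 5 with litters of 1-3 and a ~3-year
#' inter-birth interval; male reproductive success is low before physical
#' maturity around age 9.
#'
#' @param years Integer vector of simulated years; the last two are the
#'   intensive-survey window.
#' @param n0 Initial population size.
#' @param n_loci,n_screening Panel size and screening subset size.
#' @param allele_range,allele_weights Candidate per-locus allele counts and
#'   their sampling weights (defaults give a mean near 5.8).
#' @param n_mt,n_y Numbers of resident mitochondrial / Y haplotypes.
#' @param surv_cub,surv_yearling,surv_subadult Survival of ages 0 / 1 / 2-3.
#' @param surv_adult_f,surv_adult_m Adult survival by sex.
#' @param max_age_f,max_age_m Maximum attainable ages.
#' @param female_first_repro Minimum maternal age at a birth.
#' @param interbirth Minimum years between litters of one female.
#' @param litter_prob Probability an available female produces a litter.
#' @param litter_sizes,litter_weights Litter-size distribution.
#' @param male_min_repro Minimum paternal age at conception.
#' @param male_prime_age Age from which male success weight is maximal.
#' @param mixed_paternity_prob Probability each later cub of a litter draws
#'   a new father (promiscuity).
#' @param immigrant_rate Expected immigrant males per year (Poisson).
#' @param p_human_death Probability a death is human-caused (recoverable).
#' @param detect_monitor,detect_intensive Named per-method detection
#'   probabilities (`hair`, `feces`, `other`) for monitoring vs intensive
#'   years.
#' @param recover_human,recover_natural Dead-recovery probabilities by
#'   death cause.
#' @param error_rate Per-locus per-PCR mistyping rate.
#' @param replicates Independent genotyping replicates per sample; a locus
#'   is released mistyped only if every replicate errs (rate ~
#'   `error_rate^replicates`), emulating routine confirmatory re-typing.
#' @param missing_rate Per-locus amplification-failure rate for noninvasive
#'   samples.
#' @param monitoring_frac Fraction of bears whose birth year is known from
#'   continuous monitoring when they are sampled.
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(years = 1998:2020,
                       n0 = 220L,
                       n_loci = 21L,
                       n_screening = 6L,
                       allele_range = 4:8,
                       allele_weights = c(0.1, 0.3, 0.35, 0.15, 0.1),
                       n_mt = 7L,
                       n_y = 7L,
                       surv_cub = 0.70,
                       surv_yearling = 0.85,
                       surv_subadult = 0.90,
                       surv_adult_f = 0.94,
                       surv_adult_m = 0.89,
                       max_age_f = 30L,
                       max_age_m = 28L,
                       female_first_repro = 5L,
                       interbirth = 2L,
                       litter_prob = 0.55,
                       litter_sizes = 1:3,
                       litter_weights = c(0.25, 0.5, 0.25),
                       male_min_repro = 5L,
                       male_prime_age = 9L,
                       mixed_paternity_prob = 0.2,
                       immigrant_rate = 0.3,
                       p_human_death = 0.5,
                       detect_monitor = c(hair = 0.08, feces = 0.08, other = 0.01),
                       detect_intensive = c(hair = 0.45, feces = 0.30, other = 0.02),
                       recover_human = 0.95,
                       recover_natural = 0.15,
                       error_rate = 0.01,
                       replicates = 2L,
                       missing_rate = 0.02,
                       monitoring_frac = 0.3,
                       seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory")
  p <- as.list(environment())
  stopifnot(all(unlist(p[c("surv_cub", "surv_yearling", "surv_subadult",
                           "surv_adult_f", "surv_adult_m", "litter_prob",
                           "mixed_paternity_prob", "p_human_death",
                           "error_rate", "missing_rate",
                           "monitoring_frac")]) >= 0),
            all(unlist(p[c("surv_cub", "surv_yearling", "surv_subadult",
                           "surv_adult_f", "surv_adult_m", "litter_prob")]) <= 1),
            length(years) >= 3L)
  structure(p, class = "sim_params")
}

male_weight <- function(age, params) {
  ifelse(age < params$male_min_repro, 0,
         ifelse(age < params$male_prime_age, 0.15,
                ifelse(age <= 20, 1, 0.4)))
}

survival_rate_of <- function(age, sex, params) {
  ifelse(age == 0, params$surv_cub,
         ifelse(age == 1, params$surv_yearling,
                ifelse(age <= 3, params$surv_subadult,
                       ifelse(sex == "F", params$surv_adult_f,
                              params$surv_adult_m))))
}

#' Simulate a population with known ground truth
#'
#' Annual cycle: births (from the previous year's matings, so a father must
#' have been alive in the conception year), then mortality (age- and
#' sex-specific; cubs orphaned by their mother's death die with her; bears
#' reaching the maximum age die). Offspring inherit one allele from each
#' true parent at every locus, the mother's mitochondrial haplotype, and --
#' for sons -- the father's Y haplotype. Immigrant males carrying a foreign
#' mitochondrial haplotype arrive at a low Poisson rate. Deterministic
#' given the seed.
#'
#' @param params A [sim_params()].
#' @return An object of class `sim_truth`: list with `individuals` (id,
#'   sex, birth_year, death_year, death_cause, mother_id, father_id, mt,
#'   y, monitored, immigrant, entry_year), `genotypes` (true genotype
#'   matrix), `panel`, `founder_freqs`, `params`, and `extinct` flag.
#' @export
simulate_population <- function(params) {
  with_seed(params$seed, simulate_population_impl(params))
}

simulate_population_impl <- function(params) {
  years <- params$years
  panel <- default_panel(params$n_loci, params$n_screening)

  # founder allele frequencies: k alleles per locus, Dirichlet(1) weights
  k_per_locus <- sample(params$allele_range, params$n_loci, replace = TRUE,
                        prob = params$allele_weights)
  founder_freqs <- lapply(k_per_locus, function(k) {
    w <- stats::rgamma(k, shape = 1.2) + 0.05
    f <- w / sum(w)
    names(f) <- as.character(seq_len(k))
    f
  })
  names(founder_freqs) <- panel$loci

  mt_labels <- sprintf("MT-%02d", seq_len(params$n_mt))
  y_labels <- sprintf("Y-%02d", seq_len(params$n_y))
  mt_weights <- stats::rgamma(params$n_mt, shape = 1) + 0.2
  y_weights <- stats::rgamma(params$n_y, shape = 1) + 0.2

  draw_founder_geno <- function(n) {
    g <- matrix(NA_integer_, n, 2L * params$n_loci)
    for (i in seq_len(params$n_loci)) {
      f <- founder_freqs[[i]]
      a <- sample.int(length(f), n, replace = TRUE, prob = f)
      b <- sample.int(length(f), n, replace = TRUE, prob = f)
      g[, 2L * i - 1L] <- pmin(a, b)
      g[, 2L * i] <- pmax(a, b)
    }
    colnames(g) <- geno_colnames(panel)
    g
  }

  # growing state vectors
  cap <- params$n0 * 8L
  id <- character(0); sex <- character(0)
  birth <- integer(0); death <- integer(0); cause <- character(0)
  mother <- character(0); father <- character(0)
  mt <- character(0); yh <- character(0)
  monitored <- logical(0); immigrant <- logical(0); entry <- integer(0)
  geno <- list()
  n_total <- 0L
  last_litter <- new.env(parent = emptyenv())

  add_individuals <- function(n, sexes, births, mothers, fathers, mts, ys,
                              genos, immig, entries) {
    ids <- sprintf("B%05d", n_total + seq_len(n))
    id <<- c(id, ids); sex <<- c(sex, sexes)
    birth <<- c(birth, births); death <<- c(death, rep(NA_integer_, n))
    cause <<- c(cause, rep(NA_character_, n))
    mother <<- c(mother, mothers); father <<- c(father, fathers)
    mt <<- c(mt, mts); yh <<- c(yh, ys)
    monitored <<- c(monitored, stats::runif(n) < params$monitoring_frac)
    immigrant <<- c(immigrant, immig); entry <<- c(entry, entries)
    geno[[length(geno) + 1L]] <<- genos
    n_total <<- n_total + n
    ids
  }

  # founders: age structure ~ survivorship curve
  ages0 <- sample(0:20, params$n0, replace = TRUE,
                  prob = 0.92^(0:20) * c(0.7, 0.85, 0.9, 0.9, rep(1, 17)))
  sex0 <- sample(c("F", "M"), params$n0, replace = TRUE)
  mt0 <- sample(mt_labels, params$n0, replace = TRUE, prob = mt_weights)
  y0 <- ifelse(sex0 == "M",
               sample(y_labels, params$n0, replace = TRUE, prob = y_weights),
               NA_character_)
  add_individuals(params$n0, sex0, years[1] - ages0,
                  rep(NA_character_, params$n0), rep(NA_character_, params$n0),
                  mt0, y0, draw_founder_geno(params$n0),
                  rep(FALSE, params$n0), rep(years[1], params$n0))

  alive <- rep(TRUE, params$n0)
  pending_litters <- NULL  # conceived previous year, born this year
  extinct <- FALSE

  geno_all <- function() do.call(rbind, geno)

  for (t in years) {
    g <- geno_all()
    # --- births from last year's matings
    if (!is.null(pending_litters) && nrow(pending_litters) > 0L) {
      pl <- pending_litters
      mi <- match(pl$mother, id)
      ok <- alive[mi]  # mother must have survived gestation
      pl <- pl[ok, , drop = FALSE]
      if (nrow(pl) > 0L) {
        mi <- match(pl$mother, id)
        fi <- match(pl$father, id)
        n_new <- nrow(pl)
        cub_sex <- sample(c("F", "M"), n_new, replace = TRUE)
        cub_geno <- matrix(NA_integer_, n_new, 2L * params$n_loci)
        for (i in seq_len(params$n_loci)) {
          c1 <- 2L * i - 1L; c2 <- 2L * i
          ma <- ifelse(stats::runif(n_new) < 0.5, g[mi, c1], g[mi, c2])
          fa <- ifelse(stats::runif(n_new) < 0.5, g[fi, c1], g[fi, c2])
          cub_geno[, c1] <- pmin(ma, fa)
          cub_geno[, c2] <- pmax(ma, fa)
        }
        colnames(cub_geno) <- geno_colnames(panel)
        add_individuals(n_new, cub_sex, rep(t, n_new), pl$mother, pl$father,
                        mt[mi], ifelse(cub_sex == "M", yh[fi], NA_character_),
                        cub_geno, rep(FALSE, n_new), rep(t, n_new))
        alive <- c(alive, rep(TRUE, n_new))
        for (m in unique(pl$mother)) assign(m, t, envir = last_litter)
      }
      pending_litters <- NULL
    }

    # --- immigrant males
    n_imm <- stats::rpois(1, params$immigrant_rate)
    if (n_imm > 0L) {
      ages <- sample(2:5, n_imm, replace = TRUE)
      add_individuals(n_imm, rep("M", n_imm), t - ages,
                      rep(NA_character_, n_imm), rep(NA_character_, n_imm),
                      rep("MT-IMM", n_imm),
                      sample(y_labels, n_imm, replace = TRUE, prob = y_weights),
                      draw_founder_geno(n_imm), rep(TRUE, n_imm), rep(t, n_imm))
      alive <- c(alive, rep(TRUE, n_imm))
    }

    # --- mortality
    ai <- which(alive)
    if (length(ai) == 0L) { extinct <- TRUE; break }
    age <- t - birth[ai]
    s <- survival_rate_of(age, sex[ai], params)
    max_age <- ifelse(sex[ai] == "F", params$max_age_f, params$max_age_m)
    dies <- stats::runif(length(ai)) > s | age >= max_age
    died <- ai[dies]
    if (length(died)) {
      alive[died] <- FALSE
      death[died] <- t
      human <- stats::runif(length(died)) < params$p_human_death &
        (t - birth[died]) >= 1
      cause[died] <- ifelse(human, "human", "natural")
      # orphaned cubs of the year die with their mother
      dead_mothers <- id[died][sex[died] == "F"]
      if (length(dead_mothers)) {
        orphans <- which(alive & birth == t & mother %in% dead_mothers)
        if (length(orphans)) {
          alive[orphans] <- FALSE
          death[orphans] <- t
          cause[orphans] <- "natural"
        }
      }
    }

    # --- mating (conceptions; births happen next year)
    if (t < years[length(years)]) {
      ai <- which(alive)
      fem <- ai[sex[ai] == "F" & (t - birth[ai]) >= params$female_first_repro - 1L]
      # inter-birth interval: last litter must be old enough
      ok_ib <- vapply(id[fem], function(m) {
        ll <- if (exists(m, envir = last_litter)) get(m, envir = last_litter) else -Inf
        (t + 1 - ll) > params$interbirth
      }, logical(1))
      fem <- fem[ok_ib]
      males <- ai[sex[ai] == "M"]
      mw <- male_weight(t - birth[males], params)
      males <- males[mw > 0]
      mw <- mw[mw > 0]
      if (length(fem) && length(males)) {
        breeding <- fem[stats::runif(length(fem)) < params$litter_prob]
        litters <- NULL
        for (m in breeding) {
          size <- sample(params$litter_sizes, 1, prob = params$litter_weights)
          sire <- males[sample.int(length(males), 1, prob = mw)]
          sires <- rep(sire, size)
          if (size > 1L) {
            for (ci in 2:size) {
              if (stats::runif(1) < params$mixed_paternity_prob) {
                sires[ci] <- males[sample.int(length(males), 1, prob = mw)]
              }
            }
          }
          litters <- rbind(litters,
                           data.frame(mother = id[m], father = id[sires],
                                      stringsAsFactors = FALSE))
        }
        pending_litters <- litters
      }
    }
  }

  individuals <- data.frame(id = id, sex = sex, birth_year = birth,
                            death_year = death, death_cause = cause,
                            mother_id = mother, father_id = father,
                            mt = mt, y = yh, monitored = monitored,
                            immigrant = immigrant, entry_year = entry,
                            stringsAsFactors = FALSE)
  g <- geno_all()
  rownames(g) <- id
  structure(list(individuals = individuals, genotypes = g, panel = panel,
                 founder_freqs = founder_freqs, params = params,
                 extinct = extinct),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  yrs <- x$params$years
  cat("Simulated population:", nrow(x$individuals), "individuals over",
      length(yrs), "years (", yrs[1], "-", yrs[length(yrs)], ");",
      sum(alive_in(x, yrs[length(yrs) - 1L])), "alive in the reference year\n")
  invisible(x)
}

#' Individuals alive in a given year
#'
#' A bear counts as present in a year if it had entered the population by
#' then and did not die in an earlier year (bears dying during the year
#' still count, matching the census convention).
#'
#' @param truth A [simulate_population()] result.
#' @param year Calendar year.
#' @return Logical vector along `truth$individuals`.
#' @export
alive_in <- function(truth, year) {
  ind <- truth$individuals
  ind$entry_year <= year & (is.na(ind$death_year) | ind$death_year >= year)
}

#' Simulate multi-year heterogeneous sampling
#'
#' Per year, each living bear is detected by each noninvasive method with
#' its per-period detection probability (monitoring years vs the final
#' two intensive years); dead bears are recovered with a cause-dependent
#' probability, carrying an exact cementum age. Sample genotypes are the
#' truth perturbed by replicated-typing error (`error_rate^replicates` per
#' locus) and, for noninvasive samples, per-locus amplification failure.
#' Samples from monitored bears and dead recoveries carry a known birth
#' year. Deterministic given the seed in `params`.
#'
#' @param truth A [simulate_population()] result.
#' @param params The [sim_params()] used (defaults to `truth$params`).
#' @return An object of class `sim_samples`: list with `samples` (one row
#'   per sample: sample_id, year, method, true_id, known_birth_year, sex,
#'   mt, y) and `genotypes` (matrix aligned to `samples`).
#' @export
simulate_sampling <- function(truth, params = truth$params) {
  with_seed(substream_seed(params$seed, "sampling"),
            simulate_sampling_impl(truth, params))
}

simulate_sampling_impl <- function(truth, params) {
  ind <- truth$individuals
  panel <- truth$panel
  years <- params$years
  intensive <- years[c(length(years) - 1L, length(years))]
  err <- params$error_rate^params$replicates

  rows <- list()
  genos <- list()
  n <- 0L

  perturb <- function(g, missing_ok) {
    for (i in seq_along(panel$loci)) {
      c1 <- 2L * i - 1L; c2 <- 2L * i
      if (err > 0 && stats::runif(1) < err) {
        f <- truth$founder_freqs[[i]]
        a <- sample.int(length(f), 1, prob = f)
        b <- sample.int(length(f), 1, prob = f)
        g[c1] <- min(a, b); g[c2] <- max(a, b)
      }
      if (missing_ok && stats::runif(1) < params$missing_rate) {
        g[c1] <- NA_integer_; g[c2] <- NA_integer_
      }
    }
    g
  }

  emit <- function(i, year, method, with_age) {
    n <<- n + 1L
    known_birth <- if (with_age || ind$monitored[i]) ind$birth_year[i] else NA_integer_
    rows[[n]] <<- data.frame(
      sample_id = sprintf("S%06d", n), year = year, method = method,
      true_id = ind$id[i], known_birth_year = known_birth,
      sex = ind$sex[i], mt = ind$mt[i], y = ind$y[i],
      stringsAsFactors = FALSE)
    genos[[n]] <<- perturb(truth$genotypes[i, ],
                           missing_ok = method %in% c("hair", "feces"))
  }

  for (t in years) {
    det <- if (t %in% intensive) params$detect_intensive else params$detect_monitor
    present <- which(alive_in(truth, t) &
                       (is.na(ind$death_year) | ind$death_year > t))
    for (method in names(det)) {
      hit <- present[stats::runif(length(present)) < det[[method]]]
      for (i in hit) emit(i, t, method, with_age = FALSE)
    }
    dead_now <- which(!is.na(ind$death_year) & ind$death_year == t)
    for (i in dead_now) {
      p_rec <- if (ind$death_cause[i] %in% "human") params$recover_human else params$recover_natural
      if (stats::runif(1) < p_rec) emit(i, t, "dead-recovery", with_age = TRUE)
    }
  }

  samples <- if (n > 0L) do.call(rbind, rows) else
    data.frame(sample_id = character(0), year = integer(0),
               method = character(0), true_id = character(0),
               known_birth_year = integer(0), sex = character(0),
               mt = character(0), y = character(0))
  g <- if (n > 0L) do.call(rbind, genos) else
    matrix(integer(0), 0, 2L * params$n_loci,
           dimnames = list(NULL, geno_colnames(panel)))
  rownames(g) <- samples$sample_id
  structure(list(samples = samples, genotypes = g, panel = panel),
            class = "sim_samples")
}

#' @export
print.sim_samples <- function(x, ...) {
  cat("Sample stream:", nrow(x$samples), "samples;\n")
  print(table(method = x$samples$method))
  invisible(x)
}
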