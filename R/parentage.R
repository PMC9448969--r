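# Likelihood-based parentage assignment with Monte-Carlo calibrated Delta
# confidence thresholds: trio (parent-pair) assignment first, then
# single-parent assignment, with haplotype and age/liveness pre-filters and
# locus mismatch tolerances.
#
# Error model: each compared genotype call (offspring, mother, father) is,
# independently per locus, mistyped with probability e, in which case the
# observed call is a random Hardy-Weinberg genotype. Expanding over which
# calls are erroneous gives, per locus,
#   P_trio = (1-e)^3 T2 + e(1-e)^2 (T1_m + T1_f) + (e^2(1-e) + e) T0
#   P_dyad = (1-e)^2 T1 + (1 - (1-e)^2) T0
# where T2/T1/T0 are the Mendelian trio/single-parent/unrelated transition
# probabilities. At e = 0 these reduce to pure Mendelian segregation, and a
# LOD of -Inf marks an exclusion.

#' Parentage assignment configuration
#'
#' Simulation and acceptance parameters of the assignment cascade. Defaults
#' follow the standard CERVUS-style setup for a long-term bear data set:
#' 10,000 calibration cycles, 150 candidate mothers and fathers per
#' offspring, 40% of candidate parents assumed sampled, 1% of loci mistyped,
#' trio acceptance at 80% confidence with zero mismatches or at 95%
#' confidence with at most one mismatch, and single-parent acceptance at 80%
#' confidence with zero mismatches.
#'
#' @param error_rate Per-locus genotyping error rate used in likelihoods.
#' @param n_simulation_cycles Monte-Carlo cycles for Delta calibration.
#' @param n_candidates_per_offspring Candidates per offspring in calibration.
#' @param prop_candidates_sampled Probability that a true parent is present
#'   in the candidate set during calibration.
#' @param confidence_strict,confidence_relaxed Confidence levels for the
#'   strict (95%) and relaxed (80%) Delta thresholds.
#' @param trio_mismatch_max_strict,trio_mismatch_max_relaxed,dyad_mismatch_max
#'   Locus mismatch tolerances for each acceptance route.
#' @param min_parent_age Minimum age (years) of a candidate parent at the
#'   offspring's birth, applied only when both birth years are known.
#' @return A list of class `assignment_config`.
#' @export
assignment_config <- function(error_rate = 0.01,
                              n_simulation_cycles = 10000L,
                              n_candidates_per_offspring = 150L,
                              prop_candidates_sampled = 0.40,
                              confidence_strict = 0.95,
                              confidence_relaxed = 0.80,
                              trio_mismatch_max_strict = 0L,
                              trio_mismatch_max_relaxed = 1L,
                              dyad_mismatch_max = 0L,
                              min_parent_age = 4L) {
  stopifnot(error_rate >= 0, error_rate < 1,
            prop_candidates_sampled > 0, prop_candidates_sampled <= 1,
            confidence_relaxed < confidence_strict)
  structure(
    list(error_rate = error_rate,
         n_simulation_cycles = as.integer(n_simulation_cycles),
         n_candidates_per_offspring = as.integer(n_candidates_per_offspring),
         prop_candidates_sampled = prop_candidates_sampled,
         confidence_strict = confidence_strict,
         confidence_relaxed = confidence_relaxed,
         trio_mismatch_max_strict = as.integer(trio_mismatch_max_strict),
         trio_mismatch_max_relaxed = as.integer(trio_mismatch_max_relaxed),
         dyad_mismatch_max = as.integer(dyad_mismatch_max),
         min_parent_age = as.integer(min_parent_age)),
    class = "assignment_config")
}

## ---- per-locus Mendelian transition probabilities ------------------------

# p: named frequency vector; pairs are length-2 integer allele labels.
hwe_prob <- function(pair, p) {
  pa <- unname(p[as.character(pair[1])])
  pb <- unname(p[as.character(pair[2])])
  if (is.na(pa) || is.na(pb)) return(0)
  if (pair[1] == pair[2]) pa * pb else 2 * pa * pb
}

# P(offspring pair | one allele from `par`, the other from HWE)
single_parent_prob <- function(off, par, p) {
  f <- function(x) {
    if (off[1] == off[2]) {
      if (x == off[1]) unname(p[as.character(off[1])]) else 0
    } else {
      (if (x == off[1]) unname(p[as.character(off[2])]) else 0) +
        (if (x == off[2]) unname(p[as.character(off[1])]) else 0)
    }
  }
  v <- 0.5 * f(par[1]) + 0.5 * f(par[2])
  if (is.na(v)) 0 else v
}

# P(offspring pair | one allele from mother, one from father)
trio_prob <- function(off, mother, father, p) {
  hits <- 0L
  for (ma in mother) {
    for (fa in father) {
      if ((ma == off[1] && fa == off[2]) || (ma == off[2] && fa == off[1])) {
        hits <- hits + 1L
      }
    }
  }
  hits / 4
}

#' Per-locus transition probability under the genotyping-error model
#'
#' Probability of the observed offspring genotype at one locus given one or
#' two observed candidate-parent genotypes, under Mendelian segregation with
#' per-call mistyping at rate `e` (a mistyped call is replaced by a random
#' Hardy-Weinberg genotype). With a single parent, the unknown parent is
#' integrated over Hardy-Weinberg frequencies.
#'
#' @param offspring,parent,second_parent Length-2 integer allele pairs;
#'   `second_parent` may be `NULL` for the single-parent version.
#' @param freqs An [estimate_allele_frequencies()] table.
#' @param locus Locus name.
#' @param e Per-locus error rate.
#' @return Numeric probability.
#' @export
transition_prob <- function(offspring, parent, second_parent = NULL,
                            freqs, locus, e = 0) {
  p <- unclass(freqs)[[locus]]
  if (is.null(p) || length(p) == 0L) stop("no frequencies for locus ", locus)
  t0 <- hwe_prob(offspring, p)
  if (is.null(second_parent)) {
    t1 <- single_parent_prob(offspring, parent, p)
    (1 - e)^2 * t1 + (1 - (1 - e)^2) * t0
  } else {
    t2 <- trio_prob(offspring, parent, second_parent, p)
    t1m <- single_parent_prob(offspring, parent, p)
    t1f <- single_parent_prob(offspring, second_parent, p)
    (1 - e)^3 * t2 + e * (1 - e)^2 * (t1m + t1f) + (e^2 * (1 - e) + e) * t0
  }
}

#' Multilocus LOD score of a candidate parent (or parent pair)
#'
#' Sum over loci of the log likelihood ratio of the candidate(s) being the
#' parent(s) versus the offspring being unrelated (Hardy-Weinberg). Loci
#' missing in the offspring, or missing in all supplied candidates, are
#' skipped; a candidate with all loci missing therefore scores 0. In a trio,
#' a locus at which only one parent is called contributes its single-parent
#' ratio.
#'
#' @param offspring Single-row genotype.
#' @param mother,father Single-row genotypes; supply one for a dyad LOD or
#'   both for a trio LOD.
#' @param freqs Allele frequency table.
#' @param panel A [locus_panel()].
#' @param e Per-locus error rate.
#' @return Numeric LOD (natural log); `-Inf` marks a Mendelian exclusion at
#'   `e = 0`.
#' @export
lod_score <- function(offspring, mother = NULL, father = NULL,
                      freqs, panel, e = 0) {
  if (is.null(mother) && is.null(father)) stop("supply at least one candidate")
  o <- as_geno_row(offspring)
  m <- if (!is.null(mother)) as_geno_row(mother)
  f <- if (!is.null(father)) as_geno_row(father)
  tab <- unclass(freqs)
  lod <- 0
  for (i in seq_along(panel$loci)) {
    locus <- panel$loci[i]
    p <- tab[[locus]]
    if (is.null(p) || length(p) == 0L) next
    oa <- c(o[2L * i - 1L], o[2L * i])
    if (anyNA(oa)) next
    mp <- if (!is.null(m)) c(m[2L * i - 1L], m[2L * i])
    fp <- if (!is.null(f)) c(f[2L * i - 1L], f[2L * i])
    m_ok <- !is.null(mp) && !anyNA(mp)
    f_ok <- !is.null(fp) && !anyNA(fp)
    if (!m_ok && !f_ok) next
    t0 <- hwe_prob(oa, p)
    if (t0 <= 0) next
    num <- if (m_ok && f_ok) {
      transition_prob(oa, mp, fp, freqs = freqs, locus = locus, e = e)
    } else if (m_ok) {
      transition_prob(oa, mp, freqs = freqs, locus = locus, e = e)
    } else {
      transition_prob(oa, fp, freqs = freqs, locus = locus, e = e)
    }
    lod <- lod + log(num / t0)
  }
  lod
}

## ---- lookup-table engine -------------------------------------------------

# Precomputed per-locus genotype tables for fast vectorised likelihoods.
# For each locus with k alleles there are G = k(k+1)/2 unordered genotypes,
# coded 1..G; arrays T0 (G), T1 (G x G, offspring x parent) and T2
# (G x G x G, offspring x mother x father) hold Mendelian probabilities and
# LOD1/LOD2 the error-adjusted log likelihood ratios.
likelihood_tables <- function(freqs, e) {
  tab <- unclass(freqs)
  loci <- names(tab)[vapply(tab, length, 1L) > 0]
  out <- vector("list", length(loci))
  names(out) <- loci
  for (locus in loci) {
    p <- tab[[locus]]
    k <- length(p)
    idx <- which(outer(seq_len(k), seq_len(k), "<="), arr.ind = TRUE)
    a <- idx[, 1]; b <- idx[, 2]
    G <- length(a)
    alleles <- as.integer(names(p))
    t0 <- ifelse(a == b, p[a]^2, 2 * p[a] * p[b])
    t1 <- matrix(0, G, G)
    for (gp in seq_len(G)) {
      par <- c(alleles[a[gp]], alleles[b[gp]])
      for (go in seq_len(G)) {
        t1[go, gp] <- single_parent_prob(c(alleles[a[go]], alleles[b[go]]), par, p)
      }
    }
    t2 <- array(0, c(G, G, G))
    for (gm in seq_len(G)) {
      mo <- c(alleles[a[gm]], alleles[b[gm]])
      for (gf in seq_len(G)) {
        fa <- c(alleles[a[gf]], alleles[b[gf]])
        for (go in seq_len(G)) {
          t2[go, gm, gf] <- trio_prob(c(alleles[a[go]], alleles[b[go]]), mo, fa, p)
        }
      }
    }
    t1e <- (1 - e)^2 * t1 + (1 - (1 - e)^2) * t0
    lod1 <- log(t1e / t0)
    t1m <- array(t1, c(G, G, G))                 # T1[o, m] broadcast over f
    t1f <- aperm(array(t1, c(G, G, G)), c(1, 3, 2)) # T1[o, f] broadcast over m
    t2e <- (1 - e)^3 * t2 + e * (1 - e)^2 * (t1m + t1f) +
      (e^2 * (1 - e) + e) * array(t0, c(G, G, G))
    lod2 <- log(t2e / array(t0, c(G, G, G)))
    # code lookup: code_of[ai, bi] for allele indexes ai <= bi
    code_of <- matrix(NA_integer_, k, k)
    code_of[cbind(a, b)] <- seq_len(G)
    code_of[cbind(b, a)] <- seq_len(G)
    out[[locus]] <- list(alleles = alleles, a = a, b = b, G = G,
                         t0 = t0, t1 = t1, t2 = t2,
                         lod1 = lod1, lod2 = lod2, code_of = code_of)
  }
  structure(out, e = e)
}

# Encode a genotype matrix to per-locus genotype codes (n x L integer
# matrix, NA = missing or allele absent from the frequency table).
encode_genotypes <- function(genotypes, tables, panel) {
  loci <- names(tables)
  codes <- matrix(NA_integer_, nrow(genotypes), length(loci),
                  dimnames = list(rownames(genotypes), loci))
  for (j in seq_along(loci)) {
    i <- match(loci[j], panel$loci)
    tl <- tables[[j]]
    ai <- match(genotypes[, 2L * i - 1L], tl$alleles)
    bi <- match(genotypes[, 2L * i], tl$alleles)
    ok <- !is.na(ai) & !is.na(bi)
    codes[ok, j] <- tl$code_of[cbind(ai[ok], bi[ok])]
  }
  codes
}

# Vectorised dyad LODs: offspring code vector (length L) against a candidate
# code matrix (n x L). Missing loci contribute 0.
dyad_lods <- function(off_codes, cand_codes, tables) {
  n <- nrow(cand_codes)
  lod <- numeric(n)
  for (j in seq_along(tables)) {
    o <- off_codes[j]
    if (is.na(o)) next
    cc <- cand_codes[, j]
    ok <- !is.na(cc)
    if (!any(ok)) next
    lod[ok] <- lod[ok] + tables[[j]]$lod1[cbind(rep.int(o, sum(ok)), cc[ok])]
  }
  lod
}

# Vectorised trio LODs for aligned mother/father code matrices (n x L).
# A locus missing in one parent contributes that parent's dyad term.
trio_lods <- function(off_codes, mother_codes, father_codes, tables) {
  n <- nrow(mother_codes)
  lod <- numeric(n)
  for (j in seq_along(tables)) {
    o <- off_codes[j]
    if (is.na(o)) next
    tl <- tables[[j]]
    mc <- mother_codes[, j]
    fc <- father_codes[, j]
    both <- !is.na(mc) & !is.na(fc)
    monly <- !is.na(mc) & is.na(fc)
    fonly <- is.na(mc) & !is.na(fc)
    if (any(both)) {
      G <- tl$G
      lin <- o + (mc[both] - 1L) * G + (fc[both] - 1L) * G * G
      lod[both] <- lod[both] + tl$lod2[lin]
    }
    if (any(monly)) {
      lod[monly] <- lod[monly] + tl$lod1[cbind(rep.int(o, sum(monly)), mc[monly])]
    }
    if (any(fonly)) {
      lod[fonly] <- lod[fonly] + tl$lod1[cbind(rep.int(o, sum(fonly)), fc[fonly])]
    }
  }
  lod
}

# Vectorised dyad mismatch counts from codes.
dyad_mismatch_counts <- function(off_codes, cand_codes, tables) {
  n <- nrow(cand_codes)
  mm <- integer(n)
  for (j in seq_along(tables)) {
    o <- off_codes[j]
    if (is.na(o)) next
    tl <- tables[[j]]
    oa <- tl$a[o]; ob <- tl$b[o]
    cc <- cand_codes[, j]
    ok <- !is.na(cc)
    if (!any(ok)) next
    ca <- tl$a[cc[ok]]; cb <- tl$b[cc[ok]]
    bad <- ca != oa & ca != ob & cb != oa & cb != ob
    mm[ok] <- mm[ok] + bad
  }
  mm
}

# Vectorised trio mismatch counts (Mendelian probability zero at a locus).
trio_mismatch_counts <- function(off_codes, mother_codes, father_codes, tables) {
  n <- nrow(mother_codes)
  mm <- integer(n)
  for (j in seq_along(tables)) {
    o <- off_codes[j]
    if (is.na(o)) next
    tl <- tables[[j]]
    mc <- mother_codes[, j]
    fc <- father_codes[, j]
    both <- !is.na(mc) & !is.na(fc)
    monly <- !is.na(mc) & is.na(fc)
    fonly <- is.na(mc) & !is.na(fc)
    if (any(both)) {
      G <- tl$G
      lin <- o + (mc[both] - 1L) * G + (fc[both] - 1L) * G * G
      mm[both] <- mm[both] + (tl$t2[lin] == 0)
    }
    oa <- tl$a[o]; ob <- tl$b[o]
    one_side <- function(cc) {
      ca <- tl$a[cc]; cb <- tl$b[cc]
      ca != oa & ca != ob & cb != oa & cb != ob
    }
    if (any(monly)) mm[monly] <- mm[monly] + one_side(mc[monly])
    if (any(fonly)) mm[fonly] <- mm[fonly] + one_side(fc[fonly])
  }
  mm
}

# Draw n genotype codes per locus from Hardy-Weinberg proportions.
draw_hwe_codes <- function(n, tables) {
  codes <- matrix(NA_integer_, n, length(tables),
                  dimnames = list(NULL, names(tables)))
  for (j in seq_along(tables)) {
    tl <- tables[[j]]
    codes[, j] <- sample.int(tl$G, n, replace = TRUE, prob = tl$t0)
  }
  codes
}

# Draw offspring codes given parent code matrices (Mendelian, vectorised).
draw_offspring_codes <- function(mother_codes, father_codes, tables) {
  n <- nrow(mother_codes)
  codes <- matrix(NA_integer_, n, length(tables),
                  dimnames = list(NULL, names(tables)))
  for (j in seq_along(tables)) {
    tl <- tables[[j]]
    mc <- mother_codes[, j]
    fc <- father_codes[, j]
    ma <- ifelse(stats::runif(n) < 0.5, tl$a[mc], tl$b[mc])
    fa <- ifelse(stats::runif(n) < 0.5, tl$a[fc], tl$b[fc])
    lo <- pmin(ma, fa); hi <- pmax(ma, fa)
    codes[, j] <- tl$code_of[cbind(lo, hi)]
  }
  codes
}

# Mistype each call independently with probability e (HWE replacement).
perturb_codes <- function(codes, tables, e) {
  if (e <= 0) return(codes)
  for (j in seq_along(tables)) {
    tl <- tables[[j]]
    hit <- which(stats::runif(nrow(codes)) < e & !is.na(codes[, j]))
    if (length(hit)) {
      codes[hit, j] <- sample.int(tl$G, length(hit), replace = TRUE, prob = tl$t0)
    }
  }
  codes
}

## ---- Delta calibration ---------------------------------------------------

# Smallest Delta such that, among calibration cycles with Delta at or above
# it, the stated fraction of best-candidate assignments are correct.
delta_threshold <- function(delta, correct, confidence) {
  # cycles where every candidate was excluded carry no assignment at all
  delta[is.nan(delta)] <- -Inf
  o <- order(delta, decreasing = TRUE)
  frac <- cumsum(correct[o]) / seq_along(o)
  ok <- which(frac >= confidence)
  if (length(ok) == 0L) {
    warning("no Delta threshold reaches the requested confidence; using +Inf")
    return(Inf)
  }
  delta[o][max(ok)]
}

#' Calibrate Delta confidence thresholds by Monte-Carlo simulation
#'
#' Per cycle, a true mother and father are drawn from Hardy-Weinberg
#' proportions and an offspring generated by Mendelian segregation; observed
#' genotypes are mistyped at rate `error_rate`. Each true parent is present
#' in the candidate set with probability `prop_candidates_sampled`, among
#' `n_candidates_per_offspring` unrelated candidates (candidate pairs for
#' the trio analysis, single candidates for the dyad analysis). Delta is the
#' difference between the best and second-best candidate LOD; the threshold
#' for a confidence level is the smallest Delta at which that fraction of
#' at-or-above-threshold assignments is correct.
#'
#' @param config An [assignment_config()].
#' @param freqs Allele frequency table.
#' @param seed Integer seed; calibration is deterministic given the seed.
#' @return An object of class `delta_thresholds`: a 2 x 2 matrix
#'   (rows `trio`, `dyad`; columns `relaxed`, `strict`).
#' @export
calibrate_delta <- function(config, freqs, seed) {
  tables <- likelihood_tables(freqs, config$error_rate)
  if (length(tables) == 0L) stop("degenerate frequency table")
  ncyc <- config$n_simulation_cycles
  ncand <- config$n_candidates_per_offspring
  prop <- config$prop_candidates_sampled
  with_seed(seed, {
    true_m <- draw_hwe_codes(ncyc, tables)
    true_f <- draw_hwe_codes(ncyc, tables)
    off <- draw_offspring_codes(true_m, true_f, tables)
    obs_m <- perturb_codes(true_m, tables, config$error_rate)
    obs_f <- perturb_codes(true_f, tables, config$error_rate)
    obs_o <- perturb_codes(off, tables, config$error_rate)
    m_in <- stats::runif(ncyc) < prop
    f_in <- stats::runif(ncyc) < prop

    best2 <- function(lodmat) {
      best <- max.col(lodmat, ties.method = "first")
      bv <- lodmat[cbind(seq_len(nrow(lodmat)), best)]
      lodmat[cbind(seq_len(nrow(lodmat)), best)] <- -Inf
      sv <- lodmat[cbind(seq_len(nrow(lodmat)), max.col(lodmat, ties.method = "first"))]
      d <- bv - sv
      d[is.nan(d) | !is.finite(bv)] <- -Inf  # no assignable candidate
      list(best = best, delta = d)
    }

    # trio: candidate pairs, column 1 holds the true parent when sampled
    lod_t <- matrix(0, ncyc, ncand)
    mm1 <- draw_hwe_codes(ncyc, tables)  # pair column 1 fallbacks
    ff1 <- draw_hwe_codes(ncyc, tables)
    for (j in seq_along(tables)) {
      tl <- tables[[j]]
      G <- tl$G
      o <- obs_o[, j]
      m1 <- ifelse(m_in, obs_m[, j], mm1[, j])
      f1 <- ifelse(f_in, obs_f[, j], ff1[, j])
      cand_m <- matrix(sample.int(G, ncyc * (ncand - 1L), replace = TRUE, prob = tl$t0),
                       ncyc, ncand - 1L)
      cand_f <- matrix(sample.int(G, ncyc * (ncand - 1L), replace = TRUE, prob = tl$t0),
                       ncyc, ncand - 1L)
      mcods <- cbind(m1, cand_m)
      fcods <- cbind(f1, cand_f)
      lin <- o + (mcods - 1L) * G + (fcods - 1L) * G * G
      lod_t <- lod_t + matrix(tl$lod2[lin], ncyc, ncand)
    }
    bt <- best2(lod_t)
    correct_t <- bt$best == 1L & m_in & f_in

    # dyad (maternity-style): single candidates, column 1 = true mother
    lod_d <- matrix(0, ncyc, ncand)
    dd1 <- draw_hwe_codes(ncyc, tables)
    for (j in seq_along(tables)) {
      tl <- tables[[j]]
      o <- obs_o[, j]
      c1 <- ifelse(m_in, obs_m[, j], dd1[, j])
      cand <- matrix(sample.int(tl$G, ncyc * (ncand - 1L), replace = TRUE, prob = tl$t0),
                     ncyc, ncand - 1L)
      ccods <- cbind(c1, cand)
      lod_d <- lod_d + matrix(tl$lod1[cbind(rep(o, ncand), as.vector(ccods))],
                              ncyc, ncand)
    }
    bd <- best2(lod_d)
    correct_d <- bd$best == 1L & m_in

    thr <- matrix(NA_real_, 2, 2,
                  dimnames = list(c("trio", "dyad"), c("relaxed", "strict")))
    thr["trio", "relaxed"] <- delta_threshold(bt$delta, correct_t, config$confidence_relaxed)
    thr["trio", "strict"] <- delta_threshold(bt$delta, correct_t, config$confidence_strict)
    thr["dyad", "relaxed"] <- delta_threshold(bd$delta, correct_d, config$confidence_relaxed)
    thr["dyad", "strict"] <- delta_threshold(bd$delta, correct_d, config$confidence_strict)
    structure(thr, class = "delta_thresholds",
              n_cycles = ncyc, error_rate = config$error_rate)
  })
}

#' @export
print.delta_thresholds <- function(x, ...) {
  cat("Delta thresholds (", attr(x, "n_cycles"), " cycles, e = ",
      attr(x, "error_rate"), "):\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

## ---- assignment steps ----------------------------------------------------

# Delta for a LOD vector: best minus second best; a single candidate is
# compared against the unrelated baseline (LOD 0).
lod_delta <- function(lods) {
  if (length(lods) == 1L) return(lods[1L])
  s <- sort(lods, decreasing = TRUE)
  s[1L] - s[2L]
}

#' Assign a parent pair (trio step)
#'
#' Evaluates all mother x father candidate pairs. The best pair is accepted
#' at the relaxed (80%) trio Delta threshold with zero trio mismatches, or
#' at the strict (95%) threshold with at most one trio mismatch provided the
#' same mother and father are independently top-ranked (each with at most
#' one dyad mismatch) in separate maternity-only and paternity-only
#' analyses. Ties in LOD are broken deterministically by candidate id.
#'
#' @param offspring Single-row genotype of the offspring.
#' @param mothers,fathers Genotype matrices of pre-filtered candidates (row
#'   names are ids); either may be empty.
#' @param thresholds A [calibrate_delta()] result.
#' @param config An [assignment_config()].
#' @param freqs Allele frequency table.
#' @param panel A [locus_panel()].
#' @param tables Optional precomputed likelihood tables (internal reuse).
#' @return A list with `mother`, `father` (ids or `NA`), `route`, `lod`,
#'   `delta` and `mismatches`; `route` is `"trio-strict"` (zero-mismatch 80%
#'   acceptance), `"trio-relaxed"` (one-mismatch 95% acceptance) or
#'   `"none"`.
#' @export
assign_parent_pair <- function(offspring, mothers, fathers, thresholds,
                               config, freqs, panel, tables = NULL) {
  none <- list(mother = NA_character_, father = NA_character_,
               route = "none", lod = NA_real_, delta = NA_real_,
               mismatches = NA_integer_)
  if (is.null(mothers) || is.null(fathers) ||
      nrow(mothers) == 0L || nrow(fathers) == 0L) {
    return(none)
  }
  if (is.null(tables)) tables <- likelihood_tables(freqs, config$error_rate)
  # deterministic candidate order by id
  mothers <- mothers[order(rownames(mothers)), , drop = FALSE]
  fathers <- fathers[order(rownames(fathers)), , drop = FALSE]
  oc <- encode_genotypes(rbind(offspring), tables, panel)[1L, ]
  mc <- encode_genotypes(mothers, tables, panel)
  fc <- encode_genotypes(fathers, tables, panel)
  nm <- nrow(mc); nf <- nrow(fc)
  pair_m <- rep(seq_len(nm), times = nf)
  pair_f <- rep(seq_len(nf), each = nm)
  lods <- trio_lods(oc, mc[pair_m, , drop = FALSE], fc[pair_f, , drop = FALSE], tables)
  mms <- trio_mismatch_counts(oc, mc[pair_m, , drop = FALSE],
                              fc[pair_f, , drop = FALSE], tables)
  best <- which.max(lods)
  delta <- lod_delta(lods)
  lod_best <- lods[best]
  mm_best <- mms[best]
  if (!is.finite(lod_best) || lod_best <= 0) return(none)
  res <- list(mother = rownames(mc)[pair_m[best]],
              father = rownames(fc)[pair_f[best]],
              route = "none", lod = lod_best, delta = delta,
              mismatches = mm_best)
  if (mm_best <= config$trio_mismatch_max_strict &&
      delta >= thresholds["trio", "relaxed"]) {
    res$route <- "trio-strict"
    return(res)
  }
  if (mm_best <= config$trio_mismatch_max_relaxed &&
      delta >= thresholds["trio", "strict"]) {
    # the same individuals must independently top the single-parent rankings
    mlods <- dyad_lods(oc, mc, tables)
    flods <- dyad_lods(oc, fc, tables)
    mmm <- dyad_mismatch_counts(oc, mc, tables)
    fmm <- dyad_mismatch_counts(oc, fc, tables)
    top_m <- which.max(mlods)
    top_f <- which.max(flods)
    if (top_m == pair_m[best] && top_f == pair_f[best] &&
        mmm[top_m] <= 1L && fmm[top_f] <= 1L) {
      res$route <- "trio-relaxed"
      return(res)
    }
  }
  none
}

#' Assign a single parent (dyad step)
#'
#' Runs for parent slots left unassigned by the trio step: the best
#' candidate is accepted when its Delta reaches the relaxed (80%) dyad
#' threshold and it has zero dyad mismatches with the offspring.
#'
#' @inheritParams assign_parent_pair
#' @param candidates Genotype matrix of pre-filtered candidates.
#' @return A list with `parent` (id or `NA`), `lod`, `delta`, `mismatches`.
#' @export
assign_single_parent <- function(offspring, candidates, thresholds,
                                 config, freqs, panel, tables = NULL) {
  none <- list(parent = NA_character_, lod = NA_real_, delta = NA_real_,
               mismatches = NA_integer_)
  if (is.null(candidates) || nrow(candidates) == 0L) return(none)
  if (is.null(tables)) tables <- likelihood_tables(freqs, config$error_rate)
  candidates <- candidates[order(rownames(candidates)), , drop = FALSE]
  oc <- encode_genotypes(rbind(offspring), tables, panel)[1L, ]
  cc <- encode_genotypes(candidates, tables, panel)
  lods <- dyad_lods(oc, cc, tables)
  mms <- dyad_mismatch_counts(oc, cc, tables)
  best <- which.max(lods)
  delta <- lod_delta(lods)
  if (!is.finite(lods[best]) || lods[best] <= 0) return(none)
  if (mms[best] <= config$dyad_mismatch_max &&
      delta >= thresholds["dyad", "relaxed"]) {
    return(list(parent = rownames(cc)[best], lod = lods[best],
                delta = delta, mismatches = mms[best]))
  }
  none
}

#' Flag immigrant males by foreign mitochondrial haplotype
#'
#' A male whose mitochondrial haplotype is never observed in any sampled
#' female cannot have been born to a resident female and is flagged as an
#' immigrant: excluded from the candidate-offspring pool but retained as a
#' candidate father.
#'
#' @param individuals Individual table with columns `sex` and `mt`.
#' @return Logical vector.
#' @export
flag_immigrants <- function(individuals) {
  female_mts <- unique(individuals$mt[individuals$sex %in% "F" & !is.na(individuals$mt)])
  individuals$sex %in% "M" & !is.na(individuals$mt) &
    !(individuals$mt %in% female_mts)
}

#' Run the full parentage-assignment cascade
#'
#' For every candidate offspring: candidate mothers are females whose
#' mitochondrial haplotype matches the offspring's (unknown haplotypes
#' pass), candidate fathers are males, additionally Y-haplotype-matched for
#' male offspring; candidates must be alive-compatible (a mother may not die
#' before the offspring's birth year, a father not before the conception
#' year) and at least `min_parent_age` years older than the offspring when
#' both birth years are known. The trio step runs first; parent slots it
#' leaves empty go to the dyad step. If both maternity and paternity would
#' be accepted as separate dyads, only the higher-Delta one is kept so that
#' a dyad route always sets exactly one parent. Individuals of unknown sex
#' never enter candidate-parent pools; immigrant-flagged males are excluded
#' as candidate offspring but retained as candidate fathers.
#'
#' @param individuals Data frame with columns `id`, `sex` (`"F"`/`"M"`/`NA`),
#'   `mt`, `y`, `birth_year`, `death_year` (NA = not known dead),
#'   `first_id_year`, `last_id_year`; optional logical `immigrant`
#'   (computed by [flag_immigrants()] when absent).
#' @param genotypes Genotype matrix with row names matching `individuals$id`.
#' @param panel A [locus_panel()].
#' @param config An [assignment_config()].
#' @param seed Integer master seed (calibration uses a sub-stream).
#' @param freqs Optional allele frequency table (estimated from `genotypes`
#'   when `NULL`).
#' @param thresholds Optional precomputed [calibrate_delta()] result.
#' @return An object of class `parentage_table`: a data frame with one row
#'   per individual (`offspring_id`, `mother_id`, `father_id`, `route`,
#'   `lod`, `delta`, `mismatches`), with the frequency table and thresholds
#'   attached as attributes.
#' @export
run_cascade <- function(individuals, genotypes, panel, config = assignment_config(),
                        seed = 1L, freqs = NULL, thresholds = NULL) {
  if (anyDuplicated(individuals$id)) stop("duplicate individual ids")
  if (!all(individuals$id %in% rownames(genotypes))) {
    stop("genotypes missing for some individuals")
  }
  genotypes <- genotypes[individuals$id, , drop = FALSE]
  if (is.null(freqs)) freqs <- estimate_allele_frequencies(genotypes, panel)
  if (is.null(thresholds)) {
    thresholds <- calibrate_delta(config, freqs, substream_seed(seed, "calibrate"))
  }
  tables <- likelihood_tables(freqs, config$error_rate)
  if (!"immigrant" %in% names(individuals)) {
    individuals$immigrant <- flag_immigrants(individuals)
  }
  ind <- individuals
  is_f <- ind$sex %in% "F"
  is_m <- ind$sex %in% "M"

  res <- data.frame(offspring_id = ind$id,
                    mother_id = NA_character_, father_id = NA_character_,
                    route = "unassigned", lod = NA_real_, delta = NA_real_,
                    mismatches = NA_integer_, stringsAsFactors = FALSE)

  for (r in seq_len(nrow(ind))) {
    if (isTRUE(ind$immigrant[r])) next
    off <- ind[r, ]
    ob <- off$birth_year
    # maternal filter: sex, mtDNA, survival to birth year, age gap, not self
    mok <- is_f & ind$id != off$id &
      compatible_or_unknown(ind$mt, off$mt) &
      (is.na(ind$death_year) | is.na(ob) | ind$death_year >= ob) &
      (is.na(ind$birth_year) | is.na(ob) | ind$birth_year <= ob - config$min_parent_age)
    # paternal filter: sex, Y haplotype for sons, alive at conception
    fok <- is_m & ind$id != off$id &
      (is.na(ind$death_year) | is.na(ob) | ind$death_year >= ob - 1L) &
      (is.na(ind$birth_year) | is.na(ob) | ind$birth_year <= ob - config$min_parent_age)
    if (off$sex %in% "M") {
      fok <- fok & compatible_or_unknown(ind$y, off$y)
    }
    moth <- genotypes[ind$id[mok], , drop = FALSE]
    fath <- genotypes[ind$id[fok], , drop = FALSE]
    og <- genotypes[r, , drop = FALSE]

    pair <- assign_parent_pair(og, moth, fath, thresholds, config, freqs,
                               panel, tables = tables)
    if (pair$route != "none") {
      res$mother_id[r] <- pair$mother
      res$father_id[r] <- pair$father
      res$route[r] <- pair$route
      res$lod[r] <- pair$lod
      res$delta[r] <- pair$delta
      res$mismatches[r] <- pair$mismatches
      next
    }
    dm <- assign_single_parent(og, moth, thresholds, config, freqs, panel,
                               tables = tables)
    df_ <- assign_single_parent(og, fath, thresholds, config, freqs, panel,
                                tables = tables)
    m_ok <- !is.na(dm$parent)
    f_ok <- !is.na(df_$parent)
    if (m_ok && f_ok) {
      # keep the better-supported dyad only (route sets exactly one parent)
      if (dm$delta >= df_$delta) f_ok <- FALSE else m_ok <- FALSE
    }
    if (m_ok) {
      res$mother_id[r] <- dm$parent
      res$route[r] <- "dyad-mother"
      res$lod[r] <- dm$lod; res$delta[r] <- dm$delta
      res$mismatches[r] <- dm$mismatches
    } else if (f_ok) {
      res$father_id[r] <- df_$parent
      res$route[r] <- "dyad-father"
      res$lod[r] <- df_$lod; res$delta[r] <- df_$delta
      res$mismatches[r] <- df_$mismatches
    }
  }
  res <- resolve_pedigree_cycles(res, individuals)
  structure(res, class = c("parentage_table", "data.frame"),
            freqs = freqs, thresholds = thresholds, panel = panel,
            config = config)
}

# A true pedigree is acyclic, but likelihood assignment with unknown ages
# can invert a link: a bear's own child is a perfect one-allele match at
# every locus, so when the bear's real parents are unsampled (typical for
# founders) the child can top the candidate ranking. Such inversions close
# directed cycles (each bear is also assigned, correctly, as its child's
# parent). Enforce acyclicity: while a cycle exists, drop the cycle edge
# whose assigned parent entered the record latest (the likely inversion --
# real parents are identified before their offspring far more often than
# not), then relabel the offspring's route.
resolve_pedigree_cycles <- function(res, individuals) {
  first_id <- stats::setNames(individuals$first_id_year, individuals$id)
  repeat {
    cyc <- find_parent_cycle(res)
    if (is.null(cyc)) break
    # cyc: data.frame(offspring, slot, parent); drop the weakest edge
    fi <- first_id[cyc$parent]
    fi[is.na(fi)] <- -Inf  # unknown entry year: treat as long-established
    drop <- which.max(fi)
    r <- match(cyc$offspring[drop], res$offspring_id)
    res[[cyc$slot[drop]]][r] <- NA_character_
    has_m <- !is.na(res$mother_id[r])
    has_f <- !is.na(res$father_id[r])
    res$route[r] <- if (has_m && has_f) res$route[r]
    else if (has_m) "dyad-mother"
    else if (has_f) "dyad-father"
    else "unassigned"
  }
  res
}

# Find one directed cycle in the child -> parent graph, or NULL.
find_parent_cycle <- function(res) {
  ids <- res$offspring_id
  midx <- match(res$mother_id, ids)
  fidx <- match(res$father_id, ids)
  state <- integer(length(ids))  # 0 unvisited, 1 on path, 2 done
  for (start in seq_along(ids)) {
    if (state[start] != 0L) next
    # iterative DFS keeping the (node, slot) path
    stack_node <- start
    stack_edge <- 0L  # edges tried from this node: 0 none, 1 mother, 2 father
    path_slot <- NA_character_
    while (length(stack_node) > 0L) {
      top <- length(stack_node)
      v <- stack_node[top]
      state[v] <- 1L
      nxt <- NULL
      if (stack_edge[top] == 0L) {
        stack_edge[top] <- 1L
        if (!is.na(midx[v])) nxt <- list(midx[v], "mother_id")
      }
      if (is.null(nxt) && stack_edge[top] == 1L) {
        stack_edge[top] <- 2L
        if (!is.na(fidx[v])) nxt <- list(fidx[v], "father_id")
      }
      if (is.null(nxt)) {
        state[v] <- 2L
        stack_node <- stack_node[-top]
        stack_edge <- stack_edge[-top]
        path_slot <- path_slot[-top]
        next
      }
      w <- nxt[[1]]
      if (state[w] == 1L) {  # found a cycle: unwind the path from w to v
        pos <- match(w, stack_node)
        off <- ids[stack_node[pos:top]]
        slot <- c(path_slot[-seq_len(pos)][seq_len(top - pos)], nxt[[2]])
        return(data.frame(offspring = off, slot = slot,
                          parent = ids[c(stack_node[(pos + 1L):top], w)[seq_along(off)]],
                          stringsAsFactors = FALSE))
      }
      if (state[w] == 0L) {
        stack_node <- c(stack_node, w)
        stack_edge <- c(stack_edge, 0L)
        path_slot <- c(path_slot, nxt[[2]])
      }
    }
  }
  NULL
}

#' @export
print.parentage_table <- function(x, ...) {
  cat("Parentage assignments for", nrow(x), "individuals\n")
  print(table(route = x$route))
  invisible(x)
}
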