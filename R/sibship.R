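# Sibship clustering and hypothetical parents: offspring left with an empty
# parent slot by the assignment cascade are clustered into maternal/paternal
# sib groups by pairwise kinship likelihood ratios, and each group is
# explained by one hypothetical (unsampled) parent, who may thus have
# multiple offspring. This is a deliberately lightweight surrogate for a
# full-likelihood sibship reconstruction: the downstream estimator consumes
# only hypothetical-parent counts and offspring birth years.

#' Pairwise sibship log-likelihoods
#'
#' Log-likelihood of a genotype pair under three relationships, using
#' standard IBD-coefficient mixtures: unrelated k = (1, 0, 0), half-sib
#' k = (1/2, 1/2, 0), full-sib k = (1/4, 1/2, 1/4). Per locus,
#' \eqn{L(k) = P(g_1) [k_0 P_0(g_2) + k_1 P_1(g_2 | g_1) + k_2 1\{g_2 = g_1\}]},
#' where \eqn{P_1} is the single-parent-style one-allele-shared transition.
#' Genotyping error mixes each conditional with the unrelated term at rate
#' \eqn{1 - (1 - e)^2}. Loci missing in either genotype are skipped.
#'
#' @param g1,g2 Single-row genotypes.
#' @param freqs Allele frequency table.
#' @param panel A [locus_panel()].
#' @param e Per-locus error rate.
#' @return Named numeric vector of summed log-likelihoods:
#'   `full_sib`, `half_sib`, `unrelated`, plus `n_loci` used.
#' @export
pairwise_sib_lr <- function(g1, g2, freqs, panel, e = 0) {
  a <- as_geno_row(g1)
  b <- as_geno_row(g2)
  tab <- unclass(freqs)
  keep <- 1 - (1 - e)^2
  ll <- c(full_sib = 0, half_sib = 0, unrelated = 0)
  n_used <- 0L
  for (i in seq_along(panel$loci)) {
    p <- tab[[panel$loci[i]]]
    if (is.null(p) || length(p) == 0L) next
    pa <- c(a[2L * i - 1L], a[2L * i])
    pb <- c(b[2L * i - 1L], b[2L * i])
    if (anyNA(pa) || anyNA(pb)) next
    p0_1 <- hwe_prob(pa, p)
    p0_2 <- hwe_prob(pb, p)
    if (p0_1 <= 0 || p0_2 <= 0) next
    p1 <- single_parent_prob(pb, pa, p)
    ident <- as.numeric(all(sort(pa) == sort(pb)))
    l_un <- p0_1 * p0_2
    l_hs <- p0_1 * (0.5 * p0_2 + 0.5 * p1)
    l_fs <- p0_1 * (0.25 * p0_2 + 0.5 * p1 + 0.25 * ident)
    # error: with prob (1-e)^2 both calls true, else fall back to unrelated
    l_hs <- (1 - keep) * l_hs + keep * l_un
    l_fs <- (1 - keep) * l_fs + keep * l_un
    ll <- ll + log(c(l_fs, l_hs, l_un))
    n_used <- n_used + 1L
  }
  c(ll, n_loci = n_used)
}

#' Cluster unassigned offspring into sib groups per missing-parent slot
#'
#' Builds, separately for the maternal and paternal slots, a graph over the
#' offspring whose slot is empty, with an edge when the half-sib vs
#' unrelated log-likelihood ratio exceeds `threshold`, the relevant
#' haplotypes are consistent (mitochondrial for maternal groups; Y for
#' male-male pairs in paternal groups), and the already-assigned other
#' parent does not force a contradiction (a shared other parent upgrades
#' the edge test to full-sib vs unrelated). Groups are grown by merging
#' edges in order of decreasing likelihood ratio, refusing any merge that
#' would mix distinct known haplotypes within a group (two males with
#' different Y haplotypes cannot share a father even when each is
#' compatible with a linking sister), so grouping is transitive but never
#' haplotype-inconsistent -- deliberately conservative: fewer hypothetical
#' parents lower the maximum estimate.
#'
#' Offspring are expected to be restricted to the intensive-survey cohort
#' upstream; this function clusters whatever it is given.
#'
#' @param offspring_ids Character vector of offspring to cluster (subset of
#'   `individuals$id`).
#' @param individuals Individual table (columns `id`, `sex`, `mt`, `y`).
#' @param assignments A [run_cascade()] result (or compatible data frame).
#' @param genotypes Genotype matrix.
#' @param freqs Allele frequency table.
#' @param panel A [locus_panel()].
#' @param e Per-locus error rate.
#' @param threshold Half-sib vs unrelated log-LR edge threshold.
#' @return A list with elements `maternal` and `paternal`, each a list of
#'   character vectors of offspring ids (groups; singletons included).
#' @export
build_sib_groups <- function(offspring_ids, individuals, assignments,
                             genotypes, freqs, panel, e = 0.01,
                             threshold = 0) {
  idx <- match(offspring_ids, individuals$id)
  asg <- assignments[match(offspring_ids, assignments$offspring_id), ]

  group_slot <- function(slot) {
    empty <- if (slot == "maternal") is.na(asg$mother_id) else is.na(asg$father_id)
    ids <- offspring_ids[empty]
    if (length(ids) == 0L) return(list())
    sub <- individuals[match(ids, individuals$id), ]
    other_parent <- if (slot == "maternal") {
      asg$father_id[empty]
    } else {
      asg$mother_id[empty]
    }
    n <- length(ids)
    # the haplotype that constrains this slot's shared parent: mtDNA for
    # mothers (all offspring), Y for fathers (sons only)
    hap <- if (slot == "maternal") {
      sub$mt
    } else {
      ifelse(sub$sex %in% "M", sub$y, NA_character_)
    }
    edges <- NULL
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          if (!compatible_or_unknown(hap[i], hap[j])) next
          ll <- pairwise_sib_lr(genotypes[ids[i], , drop = FALSE],
                                genotypes[ids[j], , drop = FALSE],
                                freqs, panel, e)
          if (ll[["n_loci"]] == 0L) next
          same_other <- known_equal(other_parent[i], other_parent[j])
          lr <- if (same_other) {
            # same assigned other parent: sharing this slot's parent too
            # would make them full sibs
            ll[["full_sib"]] - ll[["unrelated"]]
          } else {
            ll[["half_sib"]] - ll[["unrelated"]]
          }
          if (lr > threshold) edges <- rbind(edges, c(i, j, lr))
        }
      }
    }
    # union-find, strongest edges first; a merge is refused when the two
    # groups carry different known haplotypes
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }
    grp_hap <- hap
    if (!is.null(edges)) {
      edges <- edges[order(-edges[, 3]), , drop = FALSE]
      for (k in seq_len(nrow(edges))) {
        ri <- find(as.integer(edges[k, 1])); rj <- find(as.integer(edges[k, 2]))
        if (ri == rj) next
        hi <- grp_hap[ri]; hj <- grp_hap[rj]
        if (!is.na(hi) && !is.na(hj) && hi != hj) next
        parent[rj] <- as.integer(ri)
        if (is.na(hi)) grp_hap[ri] <- hj
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    unname(split(ids, comp))
  }

  list(maternal = group_slot("maternal"), paternal = group_slot("paternal"))
}

#' Generate hypothetical parents from sib groups
#'
#' One hypothetical parent per sib group, with a namespaced id
#' (`HYP-F-001`, `HYP-M-001`, ...), the haplotype inherited from the
#' offspring where consistently determined (mitochondrial for mothers; Y
#' from sons for fathers), and an age-anchor year equal to the earliest
#' known offspring birth year (falling back to the earliest first
#' identification year, an upper bound on the birth year, which keeps age
#' lower bounds conservative).
#'
#' @param sib_groups A [build_sib_groups()] result.
#' @param individuals Individual table.
#' @return An object of class `hyp_parent_table`: data frame with columns
#'   `id`, `sex`, `offspring_ids` (list column), `haplotype`,
#'   `anchor_year`.
#' @export
generate_hypothetical_parents <- function(sib_groups, individuals) {
  build <- function(groups, sex) {
    prefix <- if (sex == "F") "HYP-F" else "HYP-M"
    n <- length(groups)
    if (n == 0L) {
      return(data.frame(id = character(0), sex = character(0),
                        haplotype = character(0), anchor_year = integer(0),
                        n_offspring = integer(0)))
    }
    out <- data.frame(id = sprintf("%s-%03d", prefix, seq_len(n)),
                      sex = rep(sex, n), haplotype = NA_character_,
                      anchor_year = NA_integer_, n_offspring = 0L,
                      stringsAsFactors = FALSE)
    offs <- vector("list", n)
    for (k in seq_len(n)) {
      ids <- groups[[k]]
      sub <- individuals[match(ids, individuals$id), ]
      hap <- if (sex == "F") sub$mt else sub$y[sub$sex %in% "M"]
      hap <- unique(hap[!is.na(hap)])
      if (length(hap) > 1L) {
        stop("internally inconsistent haplotypes in a sib group: ",
             paste(ids, collapse = ", "))
      }
      if (length(hap) == 1L) out$haplotype[k] <- hap
      anchor <- suppressWarnings(min(sub$birth_year, na.rm = TRUE))
      if (!is.finite(anchor)) {
        anchor <- suppressWarnings(min(sub$first_id_year, na.rm = TRUE))
      }
      out$anchor_year[k] <- if (is.finite(anchor)) as.integer(anchor) else NA_integer_
      out$n_offspring[k] <- length(ids)
      offs[[k]] <- ids
    }
    out$offspring_ids <- offs
    out
  }
  res <- rbind(build(sib_groups$maternal, "F"), build(sib_groups$paternal, "M"))
  structure(res, class = c("hyp_parent_table", "data.frame"))
}

#' Reconstruct the pedigree: cascade assignments plus hypothetical parents
#'
#' Convenience wrapper binding the parentage cascade and the sibship stage:
#' offspring identified in the intensive-survey window whose parent slots
#' remain empty are clustered into sib groups and the missing slots filled
#' with hypothetical parents.
#'
#' @inheritParams run_cascade
#' @param window Integer years of the intensive survey (candidate-offspring
#'   restriction for the sibship stage).
#' @param identified_years Named list (by id) of the years each individual
#'   was identified, or `NULL` to use `individuals$identified_window`.
#' @param sib_threshold Edge threshold passed to [build_sib_groups()].
#' @return An object of class `bear_pedigree`: list with `assignments`
#'   (mother/father slots filled with real or hypothetical ids or `NA`),
#'   `hypothetical` (a `hyp_parent_table`), `freqs`, `thresholds`.
#' @export
reconstruct_pedigree <- function(individuals, genotypes, panel,
                                 config = assignment_config(), seed = 1L,
                                 window = NULL, freqs = NULL,
                                 thresholds = NULL, sib_threshold = 0) {
  asg <- run_cascade(individuals, genotypes, panel, config, seed,
                     freqs = freqs, thresholds = thresholds)
  freqs <- attr(asg, "freqs")
  in_window <- if (!is.null(window) && "first_id_year" %in% names(individuals) &&
                   "identified_window" %in% names(individuals)) {
    individuals$identified_window
  } else if ("identified_window" %in% names(individuals)) {
    individuals$identified_window
  } else {
    rep(TRUE, nrow(individuals))
  }
  imm <- if ("immigrant" %in% names(individuals)) {
    individuals$immigrant
  } else {
    flag_immigrants(individuals)
  }
  cohort <- individuals$id[in_window & !imm]
  groups <- build_sib_groups(cohort, individuals, asg, genotypes, freqs,
                             panel, e = config$error_rate,
                             threshold = sib_threshold)
  hyp <- generate_hypothetical_parents(groups, individuals)
  for (k in seq_len(nrow(hyp))) {
    ids <- hyp$offspring_ids[[k]]
    rows <- match(ids, asg$offspring_id)
    if (hyp$sex[k] == "F") {
      asg$mother_id[rows] <- hyp$id[k]
    } else {
      asg$father_id[rows] <- hyp$id[k]
    }
    asg$route[rows] <- ifelse(asg$route[rows] == "unassigned" |
                                startsWith(asg$route[rows], "dyad"),
                              "sibship", asg$route[rows])
  }
  structure(list(assignments = asg, hypothetical = hyp,
                 freqs = freqs, thresholds = attr(asg, "thresholds"),
                 panel = panel, config = config),
            class = "bear_pedigree")
}

#' @export
print.bear_pedigree <- function(x, ...) {
  a <- x$assignments
  both <- sum(!is.na(a$mother_id) & !is.na(a$father_id))
  cat("Reconstructed pedigree:", nrow(a), "individuals;",
      both, "with both parents;", nrow(x$hypothetical),
      "hypothetical parents\n")
  invisible(x)
}
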