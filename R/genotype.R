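# Genotype data model: locus panels, diploid multilocus genotypes, allele
# frequencies, Mendelian mismatch counting, probability of identity, and
# sample-to-individual matching.
#
# Genotypes are stored as an integer matrix with two columns per locus
# ("<locus>.A1", "<locus>.A2"); a locus is either fully called (two alleles,
# stored sorted so that unordered pairs compare equal) or missing (both NA).
# Allele labels are opaque positive integers: fragment sizes are not modelled.

#' Define a locus panel
#'
#' A panel is the ordered set of microsatellite loci used for genotyping,
#' together with the subset used as a first-pass screening panel for
#' individual identification (a small set of highly discriminating loci that
#' every usable sample must amplify at).
#'
#' @param loci Character vector of unique locus names (length >= 1).
#' @param screening Character vector, subset of `loci`, used for screening.
#' @return An object of class `locus_panel` with elements `loci` and
#'   `screening`.
#' @examples
#' locus_panel(c("G1A", "MU05", "MU51"), screening = c("G1A", "MU05"))
#' @export
locus_panel <- function(loci, screening = loci) {
  loci <- as.character(loci)
  screening <- as.character(screening)
  if (length(loci) < 1L) stop("a panel needs at least one locus")
  if (anyDuplicated(loci)) stop("locus names must be unique")
  if (!all(screening %in% loci)) stop("screening loci must be a subset of the panel")
  structure(list(loci = loci, screening = screening), class = "locus_panel")
}

#' Default 21-locus panel with a 6-locus screening subset
#'
#' Convenience panel mirroring the common field setup: a large autosomal
#' microsatellite panel of which the first six loci form the screening panel.
#'
#' @param n_loci Number of loci.
#' @param n_screening Number of screening loci (taken from the start).
#' @return A [locus_panel()].
#' @export
default_panel <- function(n_loci = 21L, n_screening = 6L) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  locus_panel(loci, screening = loci[seq_len(min(n_screening, n_loci))])
}

#' @export
print.locus_panel <- function(x, ...) {
  cat("Locus panel:", length(x$loci), "loci;",
      length(x$screening), "screening loci\n")
  invisible(x)
}

geno_colnames <- function(panel) {
  as.vector(rbind(paste0(panel$loci, ".A1"), paste0(panel$loci, ".A2")))
}

#' Build a genotype matrix
#'
#' Validates and normalises a matrix of diploid allele calls: two integer
#' columns per locus, allele pairs sorted within locus so that unordered
#' genotypes compare equal, and a locus either fully called or fully missing.
#'
#' @param x Numeric matrix or data frame with columns `<locus>.A1`,
#'   `<locus>.A2` for every locus in `panel`, in any order. `NA` or `0` marks
#'   a missing call.
#' @param panel A [locus_panel()].
#' @return Integer matrix with normalised columns in panel order and class
#'   attribute preserved as a plain matrix; row names are kept as identifiers.
#' @export
as_genotypes <- function(x, panel) {
  cols <- geno_colnames(panel)
  x <- as.matrix(x)
  if (!all(cols %in% colnames(x))) {
    stop("genotype input lacks columns: ",
         paste(setdiff(cols, colnames(x)), collapse = ", "))
  }
  g <- matrix(as.integer(x[, cols, drop = FALSE]), nrow = nrow(x),
              dimnames = list(rownames(x), cols))
  g[!is.na(g) & g == 0L] <- NA_integer_
  # enforce per-locus all-or-nothing missingness and sorted pairs
  for (i in seq_along(panel$loci)) {
    a <- g[, 2L * i - 1L]
    b <- g[, 2L * i]
    half <- xor(is.na(a), is.na(b))
    if (any(half)) {
      a[half] <- NA_integer_
      b[half] <- NA_integer_
    }
    swap <- !is.na(a) & !is.na(b) & a > b
    if (any(swap)) {
      tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    }
    g[, 2L * i - 1L] <- a
    g[, 2L * i] <- b
  }
  g
}

# Extract the (a, b) allele pair of one row at locus index i.
locus_pair <- function(g, row, i) g[row, c(2L * i - 1L, 2L * i)]

locus_missing <- function(g, i) is.na(g[, 2L * i - 1L])

#' Estimate allele frequencies by direct counting
#'
#' Per-locus allele counts over all non-missing calls, normalised to sum to
#' one. Loci with no observations are flagged absent rather than silently
#' dropped.
#'
#' @param genotypes Genotype matrix from [as_genotypes()] (one row per
#'   individual; use consensus genotypes, not raw samples, to avoid
#'   pseudo-replication).
#' @param panel A [locus_panel()].
#' @return An object of class `allele_freq_table`: a named list with one
#'   numeric frequency vector per locus (names are allele labels), with an
#'   `absent` attribute listing unobserved loci.
#' @examples
#' panel <- locus_panel("L1")
#' g <- as_genotypes(rbind(c(1, 1), c(1, 2)) |>
#'   `colnames<-`(c("L1.A1", "L1.A2")), panel)
#' estimate_allele_frequencies(g, panel)
#' @export
estimate_allele_frequencies <- function(genotypes, panel) {
  if (is.null(dim(genotypes)) || nrow(genotypes) == 0L) {
    stop("no genotypes supplied")
  }
  any_called <- FALSE
  out <- vector("list", length(panel$loci))
  names(out) <- panel$loci
  absent <- character(0)
  for (i in seq_along(panel$loci)) {
    al <- c(genotypes[, 2L * i - 1L], genotypes[, 2L * i])
    al <- al[!is.na(al)]
    if (length(al) == 0L) {
      absent <- c(absent, panel$loci[i])
      out[[i]] <- numeric(0)
    } else {
      any_called <- TRUE
      tab <- table(al)
      f <- as.numeric(tab) / sum(tab)
      names(f) <- names(tab)
      out[[i]] <- f
    }
  }
  if (!any_called) stop("no genotypes with at least one called locus")
  structure(out, class = "allele_freq_table", absent = absent)
}

#' @export
print.allele_freq_table <- function(x, ...) {
  k <- vapply(unclass(x), length, integer(1))
  cat("Allele frequencies:", length(x), "loci; mean",
      round(mean(k[k > 0]), 2), "alleles/locus\n")
  if (length(attr(x, "absent"))) {
    cat("Absent loci:", paste(attr(x, "absent"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count parent-offspring allele mismatches (dyad)
#'
#' Number of loci, called in both genotypes, at which the candidate parent
#' shares no allele with the offspring. Missing loci are never counted.
#'
#' @param offspring,parent Single-row genotype matrices (or rows of one) on
#'   the same panel.
#' @param panel A [locus_panel()].
#' @return Integer mismatch count.
#' @export
pair_mismatches <- function(offspring, parent, panel) {
  o <- as_geno_row(offspring)
  p <- as_geno_row(parent)
  n <- 0L
  for (i in seq_along(panel$loci)) {
    oa <- o[2L * i - 1L]; ob <- o[2L * i]
    pa <- p[2L * i - 1L]; pb <- p[2L * i]
    if (is.na(oa) || is.na(pa)) next
    if (pa != oa && pa != ob && pb != oa && pb != ob) n <- n + 1L
  }
  n
}

#' Count trio allele mismatches (mother-father-offspring)
#'
#' Number of loci at which the offspring's two alleles cannot be jointly
#' explained by one allele from each parent (both assignment orders checked).
#' A locus is considered when the offspring and at least one parent are
#' called; a missing parent is allowed to supply any allele, so a trio
#' mismatch count is never below either dyad mismatch count.
#'
#' @inheritParams pair_mismatches
#' @param mother,father Single-row genotypes of the candidate parents.
#' @return Integer mismatch count.
#' @export
trio_mismatches <- function(offspring, mother, father, panel) {
  o <- as_geno_row(offspring)
  m <- as_geno_row(mother)
  f <- as_geno_row(father)
  n <- 0L
  for (i in seq_along(panel$loci)) {
    oa <- o[2L * i - 1L]; ob <- o[2L * i]
    if (is.na(oa)) next
    ma <- m[2L * i - 1L]; mb <- m[2L * i]
    fa <- f[2L * i - 1L]; fb <- f[2L * i]
    if (is.na(ma) && is.na(fa)) next
    from_m <- function(x) is.na(ma) || x == ma || x == mb
    from_f <- function(x) is.na(fa) || x == fa || x == fb
    ok <- (from_m(oa) && from_f(ob)) || (from_m(ob) && from_f(oa))
    if (!ok) n <- n + 1L
  }
  n
}

as_geno_row <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != 1L) stop("expected a single genotype row")
    x[1L, ]
  } else {
    x
  }
}

#' Probability of identity (PI)
#'
#' The probability, under Hardy-Weinberg equilibrium, that two random
#' individuals share an identical multilocus genotype:
#' the product over loci of \eqn{\sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2}.
#' Used to justify that a small screening panel discriminates individuals.
#'
#' @param freqs An [estimate_allele_frequencies()] table.
#' @param loci Character vector of loci to include (default: all with data).
#' @return Numeric probability.
#' @examples
#' # one locus with p = q = 0.5: 0.25^2 + 0.5^2 + 0.25^2 = 0.375
#' @export
probability_of_identity <- function(freqs, loci = NULL) {
  tab <- unclass(freqs)
  if (is.null(loci)) loci <- names(tab)[vapply(tab, length, 1L) > 0]
  if (length(loci) == 0L) stop("empty locus set")
  if (!all(loci %in% names(tab))) stop("unknown loci requested")
  pi_one <- function(p) {
    s2 <- sum(p^2)
    s4 <- sum(p^4)
    2 * s2^2 - s4  # equals sum p_i^4 + sum_{i<j} (2 p_i p_j)^2
  }
  prod(vapply(tab[loci], pi_one, numeric(1)))
}

#' Match a sample to the individual catalogue
#'
#' Screening-first identification: a sample missing any screening locus is
#' discarded; an exact match on the screening subset to exactly one
#' catalogued individual resolves the sample; an ambiguous or absent
#' screening match falls through to full-panel comparison; a full-panel
#' exact match (over the sample's called loci) resolves, otherwise the
#' sample represents a new individual.
#'
#' @param sample_geno Single-row genotype for the sample.
#' @param catalogue Genotype matrix of catalogued individuals (row names are
#'   ids); expected complete on the full panel.
#' @param panel A [locus_panel()].
#' @return A list with `status` (`"resolved"`, `"new"` or `"discard"`) and
#'   `id` (the resolved individual id, or `NA`).
#' @export
match_sample <- function(sample_geno, catalogue, panel) {
  s <- as_geno_row(sample_geno)
  scr_idx <- match(panel$screening, panel$loci)
  scr_cols <- as.vector(rbind(2L * scr_idx - 1L, 2L * scr_idx))
  if (anyNA(s[scr_cols])) {
    return(list(status = "discard", id = NA_character_))
  }
  if (is.null(catalogue) || nrow(catalogue) == 0L) {
    return(list(status = "new", id = NA_character_))
  }
  scr_hits <- which(colSums(t(catalogue[, scr_cols, drop = FALSE]) != s[scr_cols]) == 0L)
  if (length(scr_hits) == 1L) {
    return(list(status = "resolved", id = rownames(catalogue)[scr_hits]))
  }
  # ambiguity (>= 2 screening matches) or no screening match: full panel,
  # compared over the sample's called loci only
  called <- !is.na(s)
  cand <- if (length(scr_hits) >= 2L) scr_hits else seq_len(nrow(catalogue))
  sub <- catalogue[cand, called, drop = FALSE]
  full_hits <- cand[which(colSums(t(sub) != s[called]) == 0L)]
  if (length(full_hits) >= 1L) {
    # if two catalogued individuals are identical on the full panel they are
    # treated as one; deterministic: first id in catalogue order
    return(list(status = "resolved", id = rownames(catalogue)[full_hits[1L]]))
  }
  list(status = "new", id = NA_character_)
}
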