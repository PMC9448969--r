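# Shared fixtures: tiny panels, genotype builders and frequency tables,
# all constructed in code.

# one-row genotype matrix from an allele vector c(a1, b1, a2, b2, ...);
# NA pairs mark missing loci
g1 <- function(..., panel) {
  v <- as.integer(c(...))
  m <- matrix(v, nrow = 1)
  colnames(m) <- geno_cols(panel)
  as_genotypes(m, panel)
}

geno_cols <- function(panel) {
  as.vector(rbind(paste0(panel$loci, ".A1"), paste0(panel$loci, ".A2")))
}

# stack one-row genotypes with ids
gstack <- function(..., ids) {
  m <- do.call(rbind, list(...))
  rownames(m) <- ids
  m
}

# frequency table with k equifrequent alleles at each of n loci
uniform_freqs <- function(panel, k = 4) {
  f <- stats::setNames(rep(1 / k, k), as.character(seq_len(k)))
  structure(stats::setNames(rep(list(f), length(panel$loci)), panel$loci),
            class = "allele_freq_table", absent = character(0))
}

# random frequency table (Dirichlet-ish), deterministic under caller's seed
random_freqs <- function(panel, k = 6) {
  tab <- lapply(panel$loci, function(l) {
    w <- stats::rgamma(k, 1) + 0.1
    stats::setNames(w / sum(w), as.character(seq_len(k)))
  })
  structure(stats::setNames(tab, panel$loci),
            class = "allele_freq_table", absent = character(0))
}

# draw n multilocus genotypes from a frequency table
draw_genos <- function(n, freqs, panel, ids = sprintf("I%03d", seq_len(n))) {
  m <- matrix(NA_integer_, n, 2L * length(panel$loci))
  colnames(m) <- geno_cols(panel)
  for (i in seq_along(panel$loci)) {
    f <- unclass(freqs)[[panel$loci[i]]]
    a <- as.integer(names(f))[sample.int(length(f), n, TRUE, prob = f)]
    b <- as.integer(names(f))[sample.int(length(f), n, TRUE, prob = f)]
    m[, 2L * i - 1L] <- pmin(a, b)
    m[, 2L * i] <- pmax(a, b)
  }
  rownames(m) <- ids
  m
}

# Mendelian offspring of two genotype rows
mendel_child <- function(mother, father, panel, id = "kid") {
  m <- as.vector(mother); f <- as.vector(father)
  out <- integer(2L * length(panel$loci))
  for (i in seq_along(panel$loci)) {
    c1 <- 2L * i - 1L; c2 <- 2L * i
    ma <- if (stats::runif(1) < 0.5) m[c1] else m[c2]
    fa <- if (stats::runif(1) < 0.5) f[c1] else f[c2]
    out[c1] <- min(ma, fa); out[c2] <- max(ma, fa)
  }
  mt <- matrix(out, nrow = 1, dimnames = list(id, geno_cols(panel)))
  mt
}

# per-locus mistyping at rate e (HWE replacement), for consensus genotypes
mistype <- function(geno, freqs, panel, e) {
  for (r in seq_len(nrow(geno))) {
    for (i in seq_along(panel$loci)) {
      if (stats::runif(1) < e) {
        f <- unclass(freqs)[[panel$loci[i]]]
        a <- as.integer(names(f))[sample.int(length(f), 1, prob = f)]
        b <- as.integer(names(f))[sample.int(length(f), 1, prob = f)]
        geno[r, 2L * i - 1L] <- min(a, b)
        geno[r, 2L * i] <- max(a, b)
      }
    }
  }
  geno
}

# minimal individual table for estimator tests
ind_row <- function(id, sex, birth = NA, death = NA, first = NA, last = NA,
                    mt = NA, y = NA, win = FALSE, ref = FALSE, refp1 = FALSE) {
  data.frame(id = id, sex = sex, mt = mt, y = y,
             birth_year = as.integer(birth), death_year = as.integer(death),
             death_cause = NA_character_,
             first_id_year = as.integer(first), last_id_year = as.integer(last),
             identified_window = win, identified_ref = ref,
             identified_refp1 = refp1, immigrant = FALSE,
             stringsAsFactors = FALSE)
}

# assignment table row
asg_row <- function(off, mother = NA, father = NA, route = "unassigned") {
  data.frame(offspring_id = off, mother_id = as.character(mother),
             father_id = as.character(father), route = route,
             lod = NA_real_, delta = NA_real_, mismatches = NA_integer_,
             stringsAsFactors = FALSE)
}

empty_hyp <- function() {
  h <- data.frame(id = character(0), sex = character(0),
                  haplotype = character(0), anchor_year = integer(0),
                  n_offspring = integer(0), stringsAsFactors = FALSE)
  h$offspring_ids <- list()
  structure(h, class = c("hyp_parent_table", "data.frame"))
}

hyp_row <- function(id, sex, offspring, anchor) {
  h <- data.frame(id = id, sex = sex, haplotype = NA_character_,
                  anchor_year = as.integer(anchor),
                  n_offspring = length(offspring), stringsAsFactors = FALSE)
  h$offspring_ids <- list(offspring)
  structure(h, class = c("hyp_parent_table", "data.frame"))
}

fake_pedigree <- function(assignments, hyp = empty_hyp()) {
  structure(list(assignments = assignments, hypothetical = hyp),
            class = "bear_pedigree")
}
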