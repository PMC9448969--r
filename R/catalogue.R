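# Individual identification over a sample stream: screening-first matching
# of every sample against the growing catalogue, consensus genotypes, and
# per-individual metadata (identification years, death and age knowledge,
# haplotypes) ready for the parentage and demographic stages.

#' Build the individual catalogue from a sample stream
#'
#' Samples are processed in (year, sample id) order. A sample missing any
#' screening locus is discarded; otherwise it is matched against the
#' catalogue with [match_sample()]. Only samples complete on the full panel
#' may found a new individual (the catalogue invariant is complete
#' consensus genotypes); unmatched incomplete samples are discarded. The
#' first complete profile becomes the consensus; later samples may
#' overwrite it only when `allow_overwrite = TRUE` (re-typing from a
#' better-quality sample). Metadata accumulate per individual: first/last
#' identification years, known birth year (monitoring or cementum), death
#' year and cause (dead recovery), sex and haplotypes.
#'
#' @param samples Data frame with columns `sample_id`, `year`, `method`,
#'   `sex`, `mt`, `y`, `known_birth_year` (optional columns may be `NA`).
#' @param genotypes Genotype matrix aligned to `samples` rows (row names =
#'   sample ids).
#' @param panel A [locus_panel()].
#' @param window Integer years of the intensive survey (used to set
#'   `identified_window`, `identified_ref`, `identified_refp1`; the first
#'   window year is the reference year).
#' @param allow_overwrite Allow later complete profiles to replace the
#'   consensus genotype.
#' @return An object of class `bear_catalogue`: list with `individuals`
#'   (one row per identified bear), `genotypes` (consensus matrix),
#'   `assignments_of_samples` (sample id -> individual id or
#'   "discarded"), `panel`.
#' @export
build_catalogue <- function(samples, genotypes, panel, window = NULL,
                            allow_overwrite = FALSE) {
  ord <- order(samples$year, samples$sample_id)
  samples <- samples[ord, , drop = FALSE]
  genotypes <- genotypes[ord, , drop = FALSE]

  cat_geno <- matrix(NA_integer_, 0, ncol(genotypes),
                     dimnames = list(NULL, colnames(genotypes)))
  meta <- list()
  resolved <- rep(NA_character_, nrow(samples))

  new_meta <- function(s) {
    list(sex = s$sex, mt = s$mt, y = s$y,
         birth_year = s$known_birth_year,
         death_year = NA_integer_, death_cause = NA_character_,
         first_id_year = s$year, last_id_year = s$year,
         years = s$year)
  }
  update_meta <- function(m, s) {
    if (is.na(m$sex) && !is.na(s$sex)) m$sex <- s$sex
    if (is.na(m$mt) && !is.na(s$mt)) m$mt <- s$mt
    if (is.na(m$y) && !is.na(s$y)) m$y <- s$y
    if (is.na(m$birth_year) && !is.na(s$known_birth_year)) {
      m$birth_year <- s$known_birth_year
    }
    m$first_id_year <- min(m$first_id_year, s$year)
    m$last_id_year <- max(m$last_id_year, s$year)
    m$years <- union(m$years, s$year)
    m
  }

  for (r in seq_len(nrow(samples))) {
    s <- samples[r, ]
    g <- genotypes[r, ]
    res <- match_sample(g, cat_geno, panel)
    if (res$status == "discard") {
      resolved[r] <- "discarded"
      next
    }
    if (res$status == "new") {
      if (anyNA(g)) {  # incomplete profiles cannot found an individual
        resolved[r] <- "discarded"
        next
      }
      iid <- sprintf("C%04d", nrow(cat_geno) + 1L)
      cat_geno <- rbind(cat_geno, g)
      rownames(cat_geno)[nrow(cat_geno)] <- iid
      meta[[iid]] <- new_meta(s)
    } else {
      iid <- res$id
      meta[[iid]] <- update_meta(meta[[iid]], s)
      if (allow_overwrite && !anyNA(g) && s$method %in% c("dead-recovery", "other")) {
        cat_geno[iid, ] <- g
      }
    }
    if (s$method == "dead-recovery") {
      meta[[iid]]$death_year <- s$year
      meta[[iid]]$death_cause <- "dead"
    }
    resolved[r] <- iid
  }

  ids <- rownames(cat_geno)
  pull <- function(field, mode) {
    vapply(ids, function(i) {
      v <- meta[[i]][[field]]
      if (is.null(v) || length(v) == 0L) v <- NA
      as.vector(v, mode = mode)[1L]
    }, vector(mode, 1L), USE.NAMES = FALSE)
  }
  individuals <- data.frame(
    id = ids,
    sex = pull("sex", "character"),
    mt = pull("mt", "character"),
    y = pull("y", "character"),
    birth_year = pull("birth_year", "integer"),
    death_year = pull("death_year", "integer"),
    death_cause = pull("death_cause", "character"),
    first_id_year = pull("first_id_year", "integer"),
    last_id_year = pull("last_id_year", "integer"),
    stringsAsFactors = FALSE)
  individuals$y[!(individuals$sex %in% "M")] <- NA_character_

  if (!is.null(window)) {
    yrs <- lapply(ids, function(i) meta[[i]]$years)
    individuals$identified_window <- vapply(yrs, function(v) any(v %in% window), logical(1))
    individuals$identified_ref <- vapply(yrs, function(v) window[1] %in% v, logical(1))
    individuals$identified_refp1 <- vapply(yrs, function(v) any(v %in% window[-1]), logical(1))
  }
  individuals$immigrant <- flag_immigrants(individuals)

  structure(list(individuals = individuals, genotypes = cat_geno,
                 sample_assignments = stats::setNames(resolved, samples$sample_id),
                 panel = panel),
            class = "bear_catalogue")
}

#' @export
print.bear_catalogue <- function(x, ...) {
  disc <- sum(x$sample_assignments == "discarded", na.rm = TRUE)
  cat("Catalogue:", nrow(x$individuals), "individuals from",
      length(x$sample_assignments), "samples (", disc, "discarded )\n")
  invisible(x)
}

## ---- plain-text readers and writers --------------------------------------

#' Write / read a genotype table as TSV
#'
#' One row per individual or sample; an `id` column plus two columns per
#' locus (`<locus>.A1`, `<locus>.A2`); `0` or blank marks a missing call.
#'
#' @param genotypes Genotype matrix (row names are ids).
#' @param path File path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[is.na(df)] <- 0L
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @param panel A [locus_panel()] to validate against.
#' @export
read_genotypes_tsv <- function(path, panel) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df$id)
  g <- as_genotypes(df[setdiff(names(df), "id")], panel)
  rownames(g) <- ids
  g
}

#' Write / read the individual metadata table as CSV
#'
#' @param individuals Individual data frame.
#' @param path File path.
#' @export
write_individuals_csv <- function(individuals, path) {
  utils::write.csv(individuals, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_individuals_csv
#' @export
read_individuals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  for (col in c("birth_year", "death_year", "first_id_year", "last_id_year")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("identified_window", "identified_ref", "identified_refp1",
                "immigrant")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}
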