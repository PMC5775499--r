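#' Diploid genotype matrix
#'
#' The central container of the package: hard genotype calls for a set of
#' individuals at biallelic SNP sites with physical positions. Calls are coded
#' as alternate-allele dosage: 0 (homozygous reference), 1 (heterozygous),
#' 2 (homozygous alternate) and `NA` (missing). Positions are 1-based (VCF
#' convention) and all length arithmetic is in base pairs.
#'
#' @param calls integer matrix, individuals x sites, values in {0, 1, 2, NA}.
#' @param sites data.frame with columns `chrom` (character), `pos` (integer,
#'   strictly increasing within each chromosome block), `ref`, `alt`
#'   (single-base alleles).
#' @param individuals character vector of unique individual IDs; defaults to
#'   `rownames(calls)`.
#' @param chrom_lengths optional named integer vector of chromosome lengths in
#'   bp (used e.g. as the F_ROH denominator); carried as an attribute.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, individuals = rownames(calls),
                            chrom_lengths = NULL) {
  calls <- as.matrix(calls)
  if (is.null(individuals)) {
    individuals <- sprintf("ind%03d", seq_len(nrow(calls)))
  }
  storage.mode(calls) <- "integer"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("`sites` must have columns chrom, pos, ref, alt")
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  rownames(sites) <- NULL
  rownames(calls) <- individuals
  colnames(calls) <- NULL
  gm <- structure(
    list(calls = calls, sites = sites, individuals = as.character(individuals)),
    chrom_lengths = chrom_lengths,
    class = "genotype_matrix"
  )
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  calls <- gm$calls
  sites <- gm$sites
  if (nrow(calls) != length(gm$individuals)) {
    stop("calls row count does not match number of individuals")
  }
  if (ncol(calls) != nrow(sites)) {
    stop("calls column count does not match number of sites")
  }
  if (anyDuplicated(gm$individuals)) {
    stop("individual IDs must be unique")
  }
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  if (nrow(sites) > 0L) {
    # chromosome blocks must be contiguous, positions strictly increasing
    rle_chr <- rle(sites$chrom)
    if (anyDuplicated(rle_chr$values)) {
      stop("sites are not sorted: chromosome blocks are not contiguous")
    }
    for (chr in rle_chr$values) {
      p <- sites$pos[sites$chrom == chr]
      if (any(diff(p) <= 0L)) {
        stop("sites are not sorted: positions not strictly increasing on ", chr)
      }
    }
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d sites on %d chromosome(s)\n",
    n_ind(x), n_sites(x), length(unique(x$sites$chrom))
  ))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / sites in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_ind <- function(gm) length(gm$individuals)

#' @rdname n_ind
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Subset a genotype matrix
#'
#' Order-preserving projection onto a subset of individuals and/or sites.
#'
#' @param x a `genotype_matrix`.
#' @param individuals character vector of individual IDs to keep (must exist).
#' @param sites logical/integer index over sites, or a predicate
#'   `function(sites_df)` returning a logical vector.
#' @param ... unused.
#' @return a `genotype_matrix`.
#' @method subset genotype_matrix
#' @export
subset.genotype_matrix <- function(x, individuals = NULL, sites = NULL, ...) {
  ind_idx <- seq_len(n_ind(x))
  if (!is.null(individuals)) {
    ind_idx <- match(individuals, x$individuals)
    if (anyNA(ind_idx)) {
      stop(
        "unknown individual(s): ",
        paste(individuals[is.na(ind_idx)], collapse = ", ")
      )
    }
  }
  site_idx <- seq_len(n_sites(x))
  if (!is.null(sites)) {
    if (is.function(sites)) {
      keep <- sites(x$sites)
      if (!is.logical(keep) || length(keep) != n_sites(x)) {
        stop("site predicate must return a logical vector over all sites")
      }
      site_idx <- which(keep)
    } else if (is.logical(sites)) {
      stopifnot(length(sites) == n_sites(x))
      site_idx <- which(sites)
    } else {
      site_idx <- as.integer(sites)
    }
  }
  genotype_matrix(
    calls = x$calls[ind_idx, site_idx, drop = FALSE],
    sites = x$sites[site_idx, , drop = FALSE],
    individuals = x$individuals[ind_idx],
    chrom_lengths = attr(x, "chrom_lengths")
  )
}

#' Per-individual, per-site sequencing depth
#'
#' Read depth for every genotype call plus the number of bases of sequence each
#' site represents (`site_footprint`). The footprint default of 180 bp reflects
#' RAD loci sequenced in both directions within 90 bp of a restriction cut
#' site; it is the denominator unit for SNP-density statistics.
#'
#' @param depth non-negative integer matrix, individuals x sites.
#' @param site_footprint per-site footprint in bp (> 0), recycled if scalar.
#' @return An object of class `coverage_profile`.
#' @export
coverage_profile <- function(depth, site_footprint = 180L) {
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (any(depth < 0L, na.rm = TRUE)) stop("depth must be non-negative")
  depth[is.na(depth)] <- 0L
  site_footprint <- as.integer(rep_len(site_footprint, ncol(depth)))
  if (any(site_footprint <= 0L)) stop("site_footprint must be positive")
  structure(
    list(depth = depth, site_footprint = site_footprint),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf(
    "coverage_profile: %d individuals x %d sites, mean depth %.1f\n",
    nrow(x$depth), ncol(x$depth), mean(x$depth)
  ))
  invisible(x)
}

check_cov_aligned <- function(gm, cov) {
  if (!inherits(cov, "coverage_profile")) stop("`cov` must be a coverage_profile")
  if (nrow(cov$depth) != n_ind(gm) || ncol(cov$depth) != n_sites(gm)) {
    stop("coverage_profile dimensions do not match the genotype_matrix")
  }
  invisible(TRUE)
}

#' Demographic roles used throughout the package
#' @export
POPULATION_ROLES <- c("autochthonous", "captive", "primary", "secondary", "mixed")

#' Individual-to-population assignments with demographic roles
#'
#' @param assignments named character vector: individual ID -> population ID.
#' @param roles named character vector: population ID -> one of
#'   `r paste(POPULATION_ROLES, collapse = ", ")`.
#' @return An object of class `population_map`.
#' @export
population_map <- function(assignments, roles) {
  assignments <- vapply(assignments, as.character, character(1))
  roles <- vapply(roles, as.character, character(1))
  if (is.null(names(assignments)) || anyDuplicated(names(assignments))) {
    stop("assignments must be uniquely named by individual ID")
  }
  bad <- setdiff(unique(roles), POPULATION_ROLES)
  if (length(bad)) {
    stop(
      "unknown role(s): ", paste(bad, collapse = ", "),
      " (allowed: ", paste(POPULATION_ROLES, collapse = ", "), ")"
    )
  }
  missing_pop <- setdiff(unique(assignments), names(roles))
  if (length(missing_pop)) {
    stop("no role given for population(s): ", paste(missing_pop, collapse = ", "))
  }
  structure(list(assignments = assignments, roles = roles),
    class = "population_map"
  )
}

#' @export
print.population_map <- function(x, ...) {
  cat(sprintf(
    "population_map: %d individuals in %d population(s)\n",
    length(x$assignments), length(unique(x$assignments))
  ))
  invisible(x)
}

#' Individuals belonging to one population
#' @param popmap a `population_map`.
#' @param population population ID.
#' @return character vector of individual IDs.
#' @export
population_individuals <- function(popmap, population) {
  names(popmap$assignments)[popmap$assignments == population]
}

# Normalise a grouping argument (population_map or named character vector)
# into a named character vector individual -> group.
as_grouping <- function(groups) {
  if (inherits(groups, "population_map")) {
    return(groups$assignments)
  }
  if (is.character(groups) && !is.null(names(groups))) {
    return(groups)
  }
  stop("`groups` must be a population_map or a named character vector")
}
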