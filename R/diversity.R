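#' SNP density of a population
#'
#' Number of SNPs segregating within the population (minor allele count >= 1)
#' divided by the median sequence length covered at `depth_min` or more reads,
#' in SNPs per kilobase. The covered length is computed per individual as the
#' sum of site footprints at sites with depth >= `depth_min`; the median is
#' taken across the population's individuals (`median_scope = "individual"`).
#' The alternative reading (`"population"`) counts bp whose median depth
#' across individuals reaches the threshold.
#'
#' @param gm a [genotype_matrix()].
#' @param cov an aligned [coverage_profile()].
#' @param individuals IDs of the population's members (default: all).
#' @param depth_min minimum read depth (default 7, the per-strand RAD
#'   threshold; see [effective_cutsite_coverage()]).
#' @param median_scope see Description.
#' @return list with `n`, `snp_count`, `median_bp`, `snp_density` (per kb).
#' @export
snp_density <- function(gm, cov, individuals = NULL, depth_min = 7L,
                        median_scope = c("individual", "population")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  check_cov_aligned(gm, cov)
  median_scope <- match.arg(median_scope)
  if (is.null(individuals)) individuals <- gm$individuals
  idx <- match(individuals, gm$individuals)
  if (anyNA(idx)) stop("unknown individual(s) in population")
  if (!length(idx)) stop("population is empty")
  calls <- gm$calls[idx, , drop = FALSE]
  depth <- cov$depth[idx, , drop = FALSE]
  snp_count <- count_polymorphic(calls)
  if (median_scope == "individual") {
    bp_ind <- as.vector((depth >= depth_min) %*% cov$site_footprint)
    median_bp <- stats::median(bp_ind)
  } else {
    med_depth <- apply(depth, 2L, stats::median)
    median_bp <- sum(cov$site_footprint[med_depth >= depth_min])
  }
  if (median_bp == 0) stop("median covered sequence length is 0 bp")
  list(
    n = length(idx), snp_count = snp_count, median_bp = median_bp,
    snp_density = snp_density_value(snp_count, median_bp)
  )
}

count_polymorphic <- function(calls) {
  nn <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  sum(alt > 0L & alt < 2L * nn)
}

#' SNP density from a count and a covered length
#'
#' The arithmetic core of [snp_density()]: SNPs per kilobase of sequence.
#'
#' @param snp_count number of segregating sites.
#' @param median_bp covered sequence length in bp.
#' @return density in SNPs/kb.
#' @export
snp_density_value <- function(snp_count, median_bp) {
  if (median_bp <= 0) stop("median_bp must be > 0")
  snp_count / (median_bp / 1000)
}

#' Effective coverage at a restriction cut site
#'
#' A RAD cut site is sequenced from both directions, so a per-strand depth
#' threshold of `per_strand` corresponds to an effective site-level coverage
#' of `2 * per_strand` (7 reads per strand = 14-fold at the cut site).
#'
#' @param per_strand per-strand depth threshold.
#' @return effective site-level coverage.
#' @export
effective_cutsite_coverage <- function(per_strand = 7L) {
  2L * as.integer(per_strand)
}

#' Resampling curve of SNP density
#'
#' For every subgroup size k in 1..n-1, draws `reps` subsets of k individuals
#' without replacement and recomputes the SNP density of the draw (segregating
#' sites within the draw over the draw's median covered kilobases).
#'
#' @param gm a [genotype_matrix()].
#' @param cov an aligned [coverage_profile()].
#' @param individuals the group's members (>= 2; default: all).
#' @param reps replicates per k (default 100).
#' @param seed mandatory integer seed.
#' @param depth_min minimum read depth.
#' @return data.frame of class `resampling_curve` with columns
#'   `k`, `rep`, `snp_count`, `median_bp`, `density`.
#' @export
resample_snp_density <- function(gm, cov, individuals = NULL, reps = 100L,
                                 seed, depth_min = 7L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  check_cov_aligned(gm, cov)
  if (reps < 1L) stop("reps must be >= 1")
  if (is.null(individuals)) individuals <- gm$individuals
  idx <- match(individuals, gm$individuals)
  if (anyNA(idx)) stop("unknown individual(s) in group")
  n <- length(idx)
  if (n < 2L) stop("group size must be >= 2")
  calls <- gm$calls[idx, , drop = FALSE]
  depth <- cov$depth[idx, , drop = FALSE]
  bp_ind <- as.vector((depth >= depth_min) %*% cov$site_footprint)
  with_seed(seed, {
    rows <- vector("list", (n - 1L) * reps)
    ri <- 0L
    for (k in seq_len(n - 1L)) {
      for (r in seq_len(reps)) {
        sub <- sample.int(n, k)
        sc <- count_polymorphic(calls[sub, , drop = FALSE])
        mb <- stats::median(bp_ind[sub])
        ri <- ri + 1L
        rows[[ri]] <- c(k = k, rep = r, snp_count = sc, median_bp = mb)
      }
    }
    out <- as.data.frame(do.call(rbind, rows))
    out$density <- ifelse(out$median_bp > 0,
      out$snp_count / (out$median_bp / 1000), NA_real_
    )
    class(out) <- c("resampling_curve", class(out))
    out
  })
}

#' Per-population heterozygosity and inbreeding coefficient
#'
#' For every site, `p` is the alternate-allele frequency among the
#' population's non-missing calls; expected heterozygosity (Nei's genetic
#' diversity) is `2p(1-p)` and observed heterozygosity the fraction of
#' heterozygous calls. Population values are means over the panel's
#' polymorphic sites, and `F_IS = (He - Ho) / He` from the multilocus means
#' (`NA` when He is 0).
#'
#' @param gm a [genotype_matrix()] (the panel).
#' @param groups a [population_map()] or named character vector.
#' @param small_sample_correction multiply He by `2n/(2n-1)` per site
#'   (off by default, matching Nei's uncorrected gene diversity).
#' @return data.frame with columns population, n, sites_used, He, Ho, F_IS.
#' @export
heterozygosity_stats <- function(gm, groups, small_sample_correction = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  grouping <- as_grouping(groups)
  grouping <- grouping[gm$individuals]
  if (anyNA(grouping)) stop("grouping does not cover all individuals")
  ac <- site_allele_counts(gm$calls)
  panel_poly <- ac$alt_count > 0L & ac$alt_count < ac$total
  res <- lapply(unique(grouping), function(pop) {
    sub <- gm$calls[grouping == pop, , drop = FALSE]
    nn <- colSums(!is.na(sub))
    if (all(nn == 0L)) stop("population ", pop, " has no genotyped calls")
    use <- panel_poly & nn > 0L
    p <- colSums(sub[, use, drop = FALSE], na.rm = TRUE) / (2 * nn[use])
    he_site <- 2 * p * (1 - p)
    if (small_sample_correction) {
      he_site <- he_site * (2 * nn[use]) / (2 * nn[use] - 1)
    }
    ho_site <- colSums(sub[, use, drop = FALSE] == 1L, na.rm = TRUE) / nn[use]
    he <- if (any(use)) mean(he_site) else 0
    ho <- if (any(use)) mean(ho_site) else 0
    data.frame(
      population = pop, n = sum(grouping == pop), sites_used = sum(use),
      He = he, Ho = ho,
      F_IS = if (he > 0) (he - ho) / he else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Pairwise FST (Weir & Cockerham 1984 theta)
#'
#' Multilocus ratio-of-sums estimator from the variance components a, b, c;
#' slightly negative values are reported as computed.
#'
#' @param gm a [genotype_matrix()].
#' @param pop_a,pop_b individual IDs of the two populations (>= 2 each).
#' @return theta (numeric scalar).
#' @export
pairwise_fst <- function(gm, pop_a, pop_b) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ia <- match(pop_a, gm$individuals)
  ib <- match(pop_b, gm$individuals)
  if (anyNA(ia) || anyNA(ib)) stop("unknown individual(s)")
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("both populations need at least 2 individuals")
  }
  A <- gm$calls[ia, , drop = FALSE]
  B <- gm$calls[ib, , drop = FALSE]
  n1 <- colSums(!is.na(A))
  n2 <- colSums(!is.na(B))
  use <- n1 >= 2L & n2 >= 2L
  if (!any(use)) stop("no site genotyped in both populations")
  n1 <- n1[use]; n2 <- n2[use]
  p1 <- colSums(A[, use, drop = FALSE], na.rm = TRUE) / (2 * n1)
  p2 <- colSums(B[, use, drop = FALSE], na.rm = TRUE) / (2 * n2)
  h1 <- colSums(A[, use, drop = FALSE] == 1L, na.rm = TRUE) / n1
  h2 <- colSums(B[, use, drop = FALSE] == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}

#' PCA on the genotype covariance matrix
#'
#' Individuals and sites are filtered for genotyping rate, sites additionally
#' for minor allele frequency; dosages are mean-centered per site with missing
#' values imputed to the site mean; the individual-by-individual covariance
#' matrix is eigendecomposed. Coordinates are eigenvectors scaled by the
#' square root of their eigenvalues and are deterministic up to sign.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (strictly exceeded).
#' @param site_rate_min minimum per-site genotyping rate (strictly exceeded).
#' @param ind_rate_min minimum per-individual genotyping rate.
#' @return list with `coords` (individuals x components), `varprop`,
#'   `eigenvalues`, `n_sites_used`.
#' @export
pca_genotypes <- function(gm, maf_min = 0.05, site_rate_min = 0.8,
                          ind_rate_min = 0.8) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ind_keep <- rowMeans(!is.na(gm$calls)) >= ind_rate_min
  if (sum(ind_keep) < 2L) stop("fewer than 2 individuals pass the rate filter")
  X <- gm$calls[ind_keep, , drop = FALSE]
  nn <- colSums(!is.na(X))
  rate <- nn / nrow(X)
  alt <- colSums(X, na.rm = TRUE)
  maf <- ifelse(nn > 0, pmin(alt, 2 * nn - alt) / (2 * nn), 0)
  site_keep <- rate > site_rate_min & maf > maf_min
  if (!any(site_keep)) stop("no site passes the PCA filters")
  X <- X[, site_keep, drop = FALSE]
  m <- colMeans(X, na.rm = TRUE)
  Xc <- sweep(X, 2L, m)
  Xc[is.na(Xc)] <- 0
  C <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(C, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  coords <- e$vectors %*% diag(sqrt(lambda), nrow = length(lambda))
  rownames(coords) <- gm$individuals[ind_keep]
  colnames(coords) <- sprintf("PC%d", seq_along(lambda))
  list(
    coords = coords,
    varprop = if (sum(lambda) > 0) lambda / sum(lambda) else lambda,
    eigenvalues = lambda,
    n_sites_used = ncol(Xc)
  )
}

#' Per-population diversity report
#'
#' Combines [snp_density()] and [heterozygosity_stats()] into one table
#' with one row per population (the shape of a classic diversity table:
#' population, N, median bp sequenced, SNP count, density, He, Ho, F_IS).
#'
#' @param gm a [genotype_matrix()].
#' @param cov an aligned [coverage_profile()].
#' @param popmap a [population_map()].
#' @param depth_min minimum depth for the covered-length denominator.
#' @return data.frame, one row per population.
#' @export
diversity_table <- function(gm, cov, popmap, depth_min = 7L) {
  het <- heterozygosity_stats(gm, popmap)
  rows <- lapply(het$population, function(pop) {
    inds <- population_individuals(popmap, pop)
    sd <- snp_density(gm, cov, inds, depth_min = depth_min)
    data.frame(
      population = pop,
      role = unname(popmap$roles[pop]),
      n = sd$n,
      median_bp = sd$median_bp,
      snp_count = sd$snp_count,
      snp_density = sd$snp_density,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  cbind(out, het[, c("He", "Ho", "F_IS")])
}
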