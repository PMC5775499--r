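#' SNP panel filtering specification
#'
#' Describes which site-level filters produce a SNP panel from a raw genotype
#' matrix. Presets follow the RAD-seq panels used for ibex: `"general"`
#' (overall genotyping rate >= 45%), `"multispecies"` (rate >= 50% within
#' each group and >= 60% overall) and `"intraspecies"` (rate > 80% within
#' each group). All presets drop sites monomorphic within the grouping scope
#' and sites whose minor allele is confined to a single individual
#' (singletons and private doubletons).
#'
#' @param name preset name or `"custom"`.
#' @param group_rate_min minimum genotyping rate required within every group
#'   (0 disables).
#' @param overall_rate_min minimum genotyping rate over all individuals.
#' @param group_rate_strict if TRUE the group rate must be strictly exceeded
#'   (the intraspecies panel demands a rate *above* 80%).
#' @param remove_monomorphic drop sites with a single observed allele.
#' @param remove_singletons drop sites whose minor allele occurs in only one
#'   individual (one heterozygote, or one minor-allele homozygote).
#' @param maf_min minimum minor allele frequency, or `NULL` to disable.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(name = "custom", group_rate_min = 0,
                       overall_rate_min = 0, group_rate_strict = FALSE,
                       remove_monomorphic = TRUE, remove_singletons = TRUE,
                       maf_min = NULL) {
  stopifnot(
    group_rate_min >= 0, group_rate_min <= 1,
    overall_rate_min >= 0, overall_rate_min <= 1,
    is.null(maf_min) || (maf_min >= 0 && maf_min <= 0.5)
  )
  structure(
    list(
      name = name, group_rate_min = group_rate_min,
      overall_rate_min = overall_rate_min,
      group_rate_strict = group_rate_strict,
      remove_monomorphic = remove_monomorphic,
      remove_singletons = remove_singletons, maf_min = maf_min
    ),
    class = "panel_spec"
  )
}

#' Named panel presets
#' @param name one of "general", "multispecies", "intraspecies".
#' @return a [panel_spec()].
#' @export
panel_preset <- function(name = c("general", "multispecies", "intraspecies")) {
  name <- match.arg(name)
  switch(name,
    general = panel_spec("general", overall_rate_min = 0.45),
    multispecies = panel_spec("multispecies",
      group_rate_min = 0.5, overall_rate_min = 0.6
    ),
    intraspecies = panel_spec("intraspecies",
      group_rate_min = 0.8, group_rate_strict = TRUE
    )
  )
}

site_allele_counts <- function(calls) {
  nn <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  list(n_called = nn, alt_count = alt, total = 2L * nn)
}

#' Build a SNP panel by the stated filtering rules
#'
#' Filters are applied in a fixed order: genotyping rate (per group, then
#' overall) -> monomorphic -> singleton/private doubleton -> MAF. Minor-allele
#' classes are judged on the individuals covered by `groups` after the rate
#' filters. A singleton is a minor allele seen in exactly one heterozygous
#' individual; a private doubleton is a minor allele seen only as one
#' homozygote in one individual: both reduce to "all minor-allele copies in a
#' single individual".
#'
#' @param gm a [genotype_matrix()].
#' @param groups a [population_map()] or named character vector
#'   individual -> group; must cover all individuals of `gm`.
#' @param spec a [panel_spec()].
#' @return the filtered [genotype_matrix()] (all individuals retained).
#' @export
build_panel <- function(gm, groups, spec) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(spec, "panel_spec"))
  grouping <- as_grouping(groups)
  if (!length(grouping)) stop("empty grouping")
  missing_ind <- setdiff(gm$individuals, names(grouping))
  if (length(missing_ind)) {
    stop("grouping does not cover individual(s): ",
         paste(missing_ind, collapse = ", "))
  }
  grouping <- grouping[gm$individuals]
  keep <- rep(TRUE, n_sites(gm))
  calls <- gm$calls

  if (spec$group_rate_min > 0) {
    for (g in unique(grouping)) {
      sub <- calls[grouping == g, , drop = FALSE]
      rate <- colMeans(!is.na(sub))
      keep <- keep & if (spec$group_rate_strict) {
        rate > spec$group_rate_min
      } else {
        rate >= spec$group_rate_min
      }
    }
  }
  if (spec$overall_rate_min > 0) {
    keep <- keep & colMeans(!is.na(calls)) >= spec$overall_rate_min
  }
  ac <- site_allele_counts(calls)
  minor <- pmin(ac$alt_count, ac$total - ac$alt_count)
  if (spec$remove_monomorphic) {
    keep <- keep & ac$n_called > 0L & minor > 0L
  }
  if (spec$remove_singletons) {
    # minor allele confined to one individual: count carriers of the minor allele
    is_alt_minor <- ac$alt_count <= ac$total - ac$alt_count
    carriers <- vapply(seq_len(ncol(calls)), function(j) {
      g <- calls[, j]
      if (is_alt_minor[j]) sum(g > 0L, na.rm = TRUE) else sum(g < 2L, na.rm = TRUE)
    }, integer(1))
    keep <- keep & !(minor > 0L & carriers == 1L)
  }
  if (!is.null(spec$maf_min)) {
    maf <- ifelse(ac$total > 0L, minor / ac$total, 0)
    keep <- keep & maf >= spec$maf_min
  }
  subset(gm, sites = keep)
}

#' Drop putative paralogous sites by normalized coverage
#'
#' Depth is normalized per individual by that individual's mean depth over
#' all sites; a site is dropped when its mean normalized depth across
#' individuals is at least `fold` times the expectation (collapsed paralogs
#' attract roughly double coverage). Scale-invariant by construction.
#'
#' @param gm a [genotype_matrix()].
#' @param cov an aligned [coverage_profile()].
#' @param fold removal threshold on mean normalized depth (default 2).
#' @return the filtered [genotype_matrix()].
#' @export
coverage_paralog_filter <- function(gm, cov, fold = 2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  check_cov_aligned(gm, cov)
  ind_mean <- rowMeans(cov$depth)
  if (any(ind_mean == 0)) {
    stop("individual(s) with all-zero depth: ",
         paste(gm$individuals[ind_mean == 0], collapse = ", "))
  }
  norm <- cov$depth / ind_mean
  site_norm <- colMeans(norm)
  subset(gm, sites = site_norm < fold)
}

#' Thin sites to a minimum pairwise distance
#'
#' Greedy left-to-right per chromosome: the first site is kept, then every
#' site at least `min_bp` from the last kept site (the usual plink/vcftools
#' convention).
#'
#' @param gm a [genotype_matrix()] (sorted by construction).
#' @param min_bp minimum distance in bp between retained neighbours.
#' @return the thinned [genotype_matrix()].
#' @export
thin_by_distance <- function(gm, min_bp) {
  stopifnot(inherits(gm, "genotype_matrix"), min_bp >= 0)
  keep <- logical(n_sites(gm))
  for (chr in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == chr)
    last <- -Inf
    for (i in idx) {
      if (gm$sites$pos[i] - last >= min_bp) {
        keep[i] <- TRUE
        last <- gm$sites$pos[i]
      }
    }
  }
  subset(gm, sites = keep)
}
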