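#' Effective population size estimate container
#'
#' @param method one of "ld", "het_loss", "fst_drift".
#' @param estimate point estimate in diploid individuals (`Inf` when the
#'   signal is below the sampling expectation).
#' @param ci_lower,ci_upper confidence bounds (upper may be `Inf`).
#' @param inputs list echoing the estimator's inputs.
#' @return An object of class `ne_estimate`.
#' @export
ne_estimate <- function(method, estimate, ci_lower = NA_real_,
                        ci_upper = NA_real_, inputs = list()) {
  structure(
    list(
      method = method, estimate = estimate,
      ci_lower = ci_lower, ci_upper = ci_upper, inputs = inputs
    ),
    class = "ne_estimate"
  )
}

#' @export
print.ne_estimate <- function(x, ...) {
  ci <- if (is.na(x$ci_lower) && is.na(x$ci_upper)) {
    ""
  } else {
    sprintf(" (CI %.1f - %s)", x$ci_lower,
            if (is.infinite(x$ci_upper)) "Inf" else sprintf("%.1f", x$ci_upper))
  }
  cat(sprintf(
    "Ne estimate [%s]: %s%s\n", x$method,
    if (is.infinite(x$estimate)) "infinite" else sprintf("%.1f", x$estimate), ci
  ))
  invisible(x)
}

#' Expected sample-size component of r-squared
#'
#' The expectation of the squared locus-pair correlation attributable to the
#' finite sample alone (random-mating formulas of the LD method: the S >= 30
#' form `1/S + 3.19/S^2` and its small-sample variant).
#'
#' @param s sample size (diploid individuals).
#' @return expected r-squared under no drift signal.
#' @export
ld_sample_expectation <- function(s) {
  if (s >= 30) 1 / s + 3.19 / s^2 else 0.0018 + 0.907 / s + 4.44 / s^2
}

#' Invert mean r-squared into an LD-based Ne
#'
#' Subtracts the sample-size expectation from the mean squared correlation
#' and applies the random-mating inversion `Ne = 1 / (3 r2_drift)`. A
#' non-positive drift component yields an infinite estimate.
#'
#' @param mean_r2 mean squared locus-pair correlation.
#' @param s sample size (diploid individuals).
#' @param mating `"random"` (comparisons of unlinked loci, factor 3) or
#'   `"monogamy"` (factor 2).
#' @return Ne (possibly `Inf`).
#' @export
ld_ne_from_r2 <- function(mean_r2, s, mating = c("random", "monogamy")) {
  mating <- match.arg(mating)
  k <- if (mating == "random") 3 else 2
  r2_drift <- mean_r2 - ld_sample_expectation(s)
  if (r2_drift <= 0) Inf else 1 / (k * r2_drift)
}

#' LD-based effective population size
#'
#' Squared correlations of unphased dosages (the Burrows composite measure)
#' over all locus pairs that are either on different chromosomes or at least
#' `min_distance_bp` apart, at sites with minor allele frequency >=
#' `maf_min`; the mean r-squared is corrected for sample size and inverted
#' (see [ld_ne_from_r2()]). The confidence interval is a delete-one-individual
#' jackknife on the mean r-squared: every locus pair shares the same sampled
#' individuals, so individual resampling carries the variance that locus-block
#' resampling misses.
#'
#' @param gm a [genotype_matrix()].
#' @param individuals the population's members (>= 4; default: all).
#' @param maf_min minor allele frequency threshold (default 0.1).
#' @param min_distance_bp minimum same-chromosome pair distance (default
#'   250 kb).
#' @param mating mating system for the inversion constant.
#' @param conf confidence level for the jackknife interval.
#' @param ci compute the delete-one-individual jackknife interval (set FALSE
#'   to skip the costly resampling when only the point estimate is needed).
#' @return an [ne_estimate()] with method `"ld"`.
#' @export
ne_from_ld <- function(gm, individuals = NULL, maf_min = 0.1,
                       min_distance_bp = 250000, mating = "random",
                       conf = 0.95, ci = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(individuals)) individuals <- gm$individuals
  idx <- match(individuals, gm$individuals)
  if (anyNA(idx)) stop("unknown individual(s)")
  if (length(idx) < 4L) stop("population must have at least 4 individuals")
  X <- gm$calls[idx, , drop = FALSE]
  nn <- colSums(!is.na(X))
  alt <- colSums(X, na.rm = TRUE)
  maf <- ifelse(nn > 0, pmin(alt, 2 * nn - alt) / (2 * nn), 0)
  keep <- maf >= maf_min & nn >= 2L
  if (sum(keep) < 2L) stop("fewer than 2 loci pass the MAF filter")
  X <- X[, keep, drop = FALSE]
  chrom <- gm$sites$chrom[keep]
  pos <- gm$sites$pos[keep]
  s <- mean(colSums(!is.na(X)))

  # Burrows composite r^2: squared half-covariance of dosages over the
  # product of expected dosage variances 2*p*q (allele frequencies from the
  # retained calls). The covariance carries the n/(n-1) sample factor the
  # S-correction below was calibrated with.
  cm <- suppressWarnings(stats::cov(X, use = "pairwise.complete.obs"))
  nn_keep <- colSums(!is.na(X))
  p <- colSums(X, na.rm = TRUE) / (2 * nn_keep)
  v <- 2 * p * (1 - p)
  r2 <- (s / (s - 1))^2 * (cm / 2)^2 / outer(v / 2, v / 2)
  eligible <- matrix(TRUE, ncol(X), ncol(X))
  for (chr in unique(chrom)) {
    on_chr <- which(chrom == chr)
    if (length(on_chr) > 1L) {
      d <- abs(outer(pos[on_chr], pos[on_chr], "-"))
      eligible[on_chr, on_chr] <- d >= min_distance_bp
    }
  }
  ut <- upper.tri(r2)
  use_pair <- ut & eligible & !is.na(r2)
  n_pairs <- sum(use_pair)
  if (n_pairs < 1L) stop("no eligible locus pairs")
  mean_r2 <- mean(r2[use_pair])
  est <- ld_ne_from_r2(mean_r2, s, mating)

  # Delete-one-individual jackknife on the mean r2. All locus pairs share the
  # same sampled individuals, so individual resampling (not locus blocks)
  # carries the dominant variance component of mean r2.
  ci_lower <- NA_real_
  ci_upper <- NA_real_
  n_ind_used <- nrow(X)
  if (ci && n_ind_used >= 5L) {
    complete <- !anyNA(X)
    if (complete) {
      sxy_full <- crossprod(X)
      s1_full <- colSums(X)
    }
    loo <- vapply(seq_len(n_ind_used), function(i) {
      if (complete) {
        mean_composite_r2_complete(X, i, use_pair, sxy_full, s1_full)
      } else {
        Xi <- X[-i, , drop = FALSE]
        si <- mean(colSums(!is.na(Xi)))
        cmi <- suppressWarnings(stats::cov(Xi, use = "pairwise.complete.obs"))
        nni <- colSums(!is.na(Xi))
        pi <- colSums(Xi, na.rm = TRUE) / (2 * pmax(nni, 1L))
        vi <- pi * (1 - pi)
        r2i <- (si / (si - 1))^2 * (cmi / 2)^2 / outer(vi, vi)
        mean(r2i[use_pair], na.rm = TRUE)
      }
    }, numeric(1))
    J <- n_ind_used
    se <- sqrt((J - 1) / J * sum((loo - mean(loo))^2))
    z <- stats::qt(1 - (1 - conf) / 2, df = J - 1)
    r2_lo <- mean_r2 - z * se
    r2_hi <- mean_r2 + z * se
    ci_upper <- ld_ne_from_r2(r2_lo, s, mating)
    ci_lower <- ld_ne_from_r2(r2_hi, s, mating)
  }
  ne_estimate(
    "ld", est, ci_lower, ci_upper,
    inputs = list(
      maf_min = maf_min, min_distance_bp = min_distance_bp,
      s = s, n_loci = ncol(X), n_pairs = n_pairs, mean_r2 = mean_r2,
      mating = mating
    )
  )
}

#' Mean composite r2 with individual i removed, complete data only.
#' Downdates the crossproduct rather than recomputing the covariance matrix.
#' @noRd
mean_composite_r2_complete <- function(X, i, use_pair, sxy_full, s1_full) {
  n <- nrow(X) - 1L
  s1 <- s1_full - X[i, ]
  sxy <- sxy_full - tcrossprod(X[i, ])
  m <- s1 / n
  cm <- (sxy - n * tcrossprod(m)) / (n - 1)
  p <- s1 / (2 * n)
  v <- p * (1 - p)
  r2 <- (n / (n - 1))^2 * (cm / 2)^2 / outer(v, v)
  mean(r2[use_pair], na.rm = TRUE)
}

#' Ne from heterozygosity loss
#'
#' Inverts the per-generation decay `H_{t+1} = (1 - 1/(2 Ne)) H_t`:
#' `Ne = 1 / (2 (1 - (ht/h0)^(1/t)))`. Equal heterozygosities give an
#' infinite estimate.
#'
#' @param h0 heterozygosity at the start.
#' @param ht heterozygosity after `t` generations (0 < ht <= h0).
#' @param t generations (>= 1).
#' @return an [ne_estimate()] with method `"het_loss"`.
#' @export
ne_from_het_loss <- function(h0, ht, t) {
  if (t < 1) stop("t must be >= 1")
  if (ht <= 0 || h0 <= 0) stop("heterozygosities must be positive")
  if (ht > h0) stop("ht exceeds h0: heterozygosity cannot increase under drift")
  ratio <- ht / h0
  est <- if (ratio == 1) Inf else 1 / (2 * (1 - ratio^(1 / t)))
  ne_estimate("het_loss", est, inputs = list(h0 = h0, ht = ht, t = t))
}

#' Ne from FST accumulated by drift
#'
#' Inverts Wright's divergence equation `1 - FST = (1 - 1/(2 Ne))^t`
#' (no differentiation at time zero): `Ne = 1 / (2 (1 - (1 - fst)^(1/t)))`.
#'
#' @param fst pairwise FST in [0, 1).
#' @param t generations since divergence (>= 1).
#' @return an [ne_estimate()] with method `"fst_drift"`.
#' @export
ne_from_fst_drift <- function(fst, t) {
  if (t < 1) stop("t must be >= 1")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  est <- if (fst == 0) Inf else 1 / (2 * (1 - (1 - fst)^(1 / t)))
  ne_estimate("fst_drift", est, inputs = list(fst = fst, t = t))
}

#' FST expected under pure drift
#'
#' Forward form of Wright's equation: `1 - (1 - 1/(2 ne))^t`.
#'
#' @param ne effective size (>= 1).
#' @param t generations (>= 0).
#' @return expected FST.
#' @export
fst_expected_under_drift <- function(ne, t) {
  if (ne < 1) stop("ne must be >= 1")
  if (t < 0) stop("t must be >= 0")
  1 - (1 - 1 / (2 * ne))^t
}

#' Drift FST from allele frequencies
#'
#' Variance-standardised differentiation between allele-frequency vectors,
#' for simulator-consistency checks against Wright's equation.
#' With `ancestral = TRUE`, `p1` is the (essentially undrifted) ancestral
#' frequency and `F = sum(d^2) / sum(p1 (1 - p1))` estimates the descendant's
#' accumulated drift. With `ancestral = FALSE` both populations drifted from
#' a common unknown ancestor and the infinite-sample variance-components form
#' `F = sum(d^2) / (2 sum(pbar qbar + d^2 / 4))` is used; its expectation is
#' the per-population `1 - (1 - 1/(2 Ne))^t` when both sides share Ne.
#'
#' @param p1,p2 allele-frequency vectors of equal length.
#' @param ancestral is `p1` the ancestral frequency itself?
#' @return drift FST (numeric scalar).
#' @export
drift_fst <- function(p1, p2, ancestral = FALSE) {
  stopifnot(length(p1) == length(p2))
  d <- p2 - p1
  if (ancestral) {
    den <- p1 * (1 - p1)
    use <- den > 0
    if (!any(use)) stop("no polymorphic ancestral locus")
    sum(d[use]^2) / sum(den[use])
  } else {
    pbar <- (p1 + p2) / 2
    den <- pbar * (1 - pbar) + d^2 / 4
    use <- den > 0
    if (!any(use)) stop("no polymorphic locus")
    sum(d[use]^2) / (2 * sum(den[use]))
  }
}
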