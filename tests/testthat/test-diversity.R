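test_that("snp_density arithmetic matches direct computation", {
  # 10 SNPs over a median of 5,000 bp -> 2.0 SNPs/kb
  expect_equal(snp_density_value(10, 5000), 2.0)
  expect_error(snp_density_value(10, 0), "must be > 0")

  # full operation on a constructed fixture: 3 individuals, 12 sites with
  # footprint 500 bp, each individual covered (>= 7 reads) at exactly 10
  # sites; 10 of the sites polymorphic
  calls <- matrix(0L, 3, 12)
  calls[1, 1:10] <- 1L                    # sites 1..10 polymorphic
  depth <- matrix(10L, 3, 12)
  depth[, 11:12] <- 2L                    # two sites below threshold
  gm <- make_gm(calls)
  cov <- coverage_profile(depth, site_footprint = 500L)
  res <- snp_density(gm, cov)
  expect_equal(res$snp_count, 10L)
  expect_equal(res$median_bp, 5000)
  expect_equal(res$snp_density, 2.0)

  # no polymorphic sites -> density 0
  res0 <- snp_density(make_gm(matrix(0L, 3, 12)), cov)
  expect_equal(res0$snp_density, 0)
})

test_that("per-strand threshold of 7 corresponds to 14x cut-site coverage", {
  expect_identical(effective_cutsite_coverage(7L), 14L)
})

test_that("resampled SNP counts match exhaustive subset enumeration", {
  # 3 individuals, enumerable C(3,2) subsets at k = 2
  calls <- cbind(
    c(1L, 0L, 0L),
    c(0L, 1L, 2L),
    c(0L, 0L, 0L),
    c(2L, 2L, 0L),
    c(1L, 1L, 1L)
  )
  gm <- make_gm(calls)
  cov <- coverage_profile(matrix(10L, 3, 5), site_footprint = 200L)
  exact_counts <- sapply(list(c(1, 2), c(1, 3), c(2, 3)), function(sub) {
    cc <- calls[sub, , drop = FALSE]
    nn <- colSums(!is.na(cc))
    alt <- colSums(cc)
    sum(alt > 0 & alt < 2 * nn)
  })
  cur <- resample_snp_density(gm, cov, reps = 300L, seed = 1)
  got <- cur$snp_count[cur$k == 2L]
  exact_mean <- mean(exact_counts)
  tol <- 3 * stats::sd(got) / sqrt(length(got)) + 1e-9
  expect_lt(abs(mean(got) - exact_mean), max(tol, 0.05))
  expect_identical(nrow(cur), 2L * 300L)   # k in {1, 2}, 300 replicates each

  # identical homozygous individuals -> every replicate density 0
  flat <- make_gm(matrix(2L, 4, 5))
  cur0 <- resample_snp_density(flat, coverage_profile(matrix(9L, 4, 5)),
                               reps = 20L, seed = 2)
  expect_true(all(cur0$density == 0))
  expect_error(resample_snp_density(gm, cov, reps = 0L, seed = 1), "reps")
})

test_that("median resampled density is non-decreasing in k (no-missing fixture)", {
  gm <- random_gm(21, n = 8, L = 80, miss = 0)
  cov <- coverage_profile(matrix(10L, 8, 80), site_footprint = 100L)
  cur <- resample_snp_density(gm, cov, reps = 60L, seed = 3)
  med <- tapply(cur$density, cur$k, stats::median)
  expect_true(all(diff(med) >= 0))
})

test_that("heterozygosity statistics agree with per-site hand computation", {
  # forced values: two individuals, both heterozygous at the single site
  gm2 <- make_gm(matrix(1L, 2, 1))
  res2 <- heterozygosity_stats(gm2, setNames(c("p", "p"), gm2$individuals))
  expect_equal(res2$He, 0.5)
  expect_equal(res2$Ho, 1.0)
  expect_equal(res2$F_IS, -1)

  # all homozygous-reference: He undefined, flagged as NA
  gm0 <- make_gm(matrix(0L, 3, 4))
  res0 <- heterozygosity_stats(gm0, setNames(rep("p", 3), gm0$individuals))
  expect_equal(res0$He, 0)
  expect_true(is.na(res0$F_IS))

  # 4-individual, 3-site printed toy vs hand computation
  calls <- cbind(c(0L, 1L, 1L, 2L),   # p = 4/8 = 0.5, He = .5, Ho = .5
                 c(0L, 0L, 1L, 0L),   # p = 1/8,  He = 2*(1/8)*(7/8), Ho = .25
                 c(2L, 2L, 1L, NA))   # p = 5/6,  He = 2*(5/6)*(1/6), Ho = 1/3
  gm <- make_gm(calls)
  res <- heterozygosity_stats(gm, setNames(rep("p", 4), gm$individuals))
  he_hand <- mean(c(2 * .5 * .5, 2 * (1 / 8) * (7 / 8), 2 * (5 / 6) * (1 / 6)))
  ho_hand <- mean(c(0.5, 0.25, 1 / 3))
  expect_equal(res$He, he_hand)
  expect_equal(res$Ho, ho_hand)
  expect_equal(res$F_IS, (he_hand - ho_hand) / he_hand)

  expect_error(
    heterozygosity_stats(make_gm(matrix(NA_integer_, 2, 2)),
                         setNames(rep("p", 2), c("i01", "i02"))),
    "no genotyped calls"
  )
})

test_that("Weir-Cockerham theta matches the brute-force oracle and edge cases", {
  set.seed(10)
  for (rep in 1:5) {
    gm <- random_gm(rep + 30, n = 10, L = 50, miss = 0.1)
    a <- gm$individuals[1:5]
    b <- gm$individuals[6:10]
    got <- pairwise_fst(gm, a, b)
    want <- oracle_wc_fst(gm$calls[1:5, ], gm$calls[6:10, ])
    expect_equal(got, want, tolerance = 1e-12)
  }
  # fixed for alternative alleles -> theta = 1
  fixed <- make_gm(rbind(matrix(0L, 4, 6), matrix(2L, 4, 6)))
  expect_equal(pairwise_fst(fixed, fixed$individuals[1:4],
                            fixed$individuals[5:8]), 1)
  expect_error(pairwise_fst(fixed, fixed$individuals[1], fixed$individuals[5:8]),
               "at least 2")
})

test_that("two samples from one panmictic population give FST near 0 and F_IS near 0", {
  dem <- single_pop_demography(200, 3)
  gen <- unlinked_genome(2000)
  sim <- simulate_reintroduction(dem, gen, seed = 5, sample_n = 40)
  gm <- sim$stages$pop$genotypes
  theta <- pairwise_fst(gm, gm$individuals[1:20], gm$individuals[21:40])
  expect_lt(abs(theta), 0.02)
  fis <- heterozygosity_stats(gm, setNames(rep("p", 40), gm$individuals))$F_IS
  expect_lt(abs(fis), 0.05)
})

test_that("PCA coordinates behave as an eigendecomposition of the covariance", {
  # duplicate individuals land on identical coordinates
  base <- random_gm(77, n = 6, L = 60, miss = 0)
  calls <- rbind(base$calls, base$calls[1, , drop = FALSE])
  gm <- make_gm(calls, pos = base$sites$pos, chrom = base$sites$chrom)
  res <- pca_genotypes(gm, maf_min = 0, site_rate_min = 0)
  expect_equal(res$coords[1, ], res$coords[7, ], tolerance = 1e-8)
  expect_true(all(res$varprop >= 0))
  expect_lte(sum(res$varprop), 1 + 1e-12)

  # 3-individual, 2-site toy against a closed-form eigendecomposition
  toy <- make_gm(cbind(c(0L, 1L, 2L), c(2L, 1L, 0L)))
  got <- pca_genotypes(toy, maf_min = 0, site_rate_min = 0)
  X <- cbind(c(0, 1, 2), c(2, 1, 0))
  Xc <- sweep(X, 2, colMeans(X))
  C <- tcrossprod(Xc) / 2
  e <- eigen(C, symmetric = TRUE)
  want <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  for (k in 1:2) {
    expect_true(
      isTRUE(all.equal(got$coords[, k], want[, k], tolerance = 1e-8,
                       check.attributes = FALSE)) ||
      isTRUE(all.equal(got$coords[, k], -want[, k], tolerance = 1e-8,
                       check.attributes = FALSE))
    )
  }
  expect_error(pca_genotypes(make_gm(matrix(c(0L, 2L), 2, 1)),
                             maf_min = 0, site_rate_min = 0,
                             ind_rate_min = 2), "fewer than 2")
})
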