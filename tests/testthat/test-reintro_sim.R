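test_that("the ibex demography preset has the documented structure", {
  dem <- default_ibex_demography()
  st <- dem$stages
  expect_identical(sum(is.na(st$parent)), 1L)
  expect_identical(st$founders[st$id == "captive"], 88L)
  sec <- st[st$role == "secondary", ]
  expect_gte(nrow(sec), 2L)
  expect_true(all(st$role[match(sec$parent, st$id)] == "primary"))
  expect_true(all(st$generations[st$role %in% c("primary", "secondary")] == 10L))
  # invalid graphs are rejected
  expect_error(demography_model(data.frame(
    id = c("a", "b"), parent = c("b", "a"), founders = c(5L, 5L),
    ne = c(10L, 10L), generations = c(1L, 1L), role = "primary"
  )), "root")
  expect_error(demography_model(data.frame(
    id = c("a", "b"), parent = c(NA, "a"), founders = c(NA, 50L),
    ne = c(10L, 50L), generations = c(1L, 1L),
    role = c("autochthonous", "primary")
  )), "founder count exceeds")
})

test_that("simulation is reproducible and requires a seed", {
  dem <- single_pop_demography(20, 2)
  gen <- unlinked_genome(50)
  s1 <- simulate_reintroduction(dem, gen, seed = 7)
  s2 <- simulate_reintroduction(dem, gen, seed = 7)
  expect_identical(s1$stages$pop$genotypes$calls, s2$stages$pop$genotypes$calls)
  s3 <- simulate_reintroduction(dem, gen, seed = 8)
  expect_false(identical(s1$stages$pop$genotypes$calls,
                         s3$stages$pop$genotypes$calls))
  expect_error(simulate_reintroduction(dem, gen), "seed is mandatory")
})

test_that("founding without drift keeps allele frequencies in expectation", {
  # generations = 0 everywhere: sampled founders' frequencies are unbiased
  dem <- demography_model(data.frame(
    id = c("src", "daughter"), parent = c(NA, "src"),
    founders = c(NA, 30L), ne = c(100L, 30L), generations = c(0L, 0L),
    role = c("autochthonous", "primary")
  ))
  gen <- unlinked_genome(200)
  devs <- unlist(lapply(1:5, function(s) {
    sim <- simulate_reintroduction(dem, gen, seed = s)
    sim$stages$daughter$freq_founding - sim$init_freq
  }))
  # MC standard error of the mean deviation over 5 x 200 loci at n = 30
  se <- sqrt(mean(0.5 * 0.5 / 60) / length(devs))
  expect_lt(abs(mean(devs)), 3 * se)
})

test_that("heterozygosity decays as H0 (1 - 1/(2Ne))^t (closed form)", {
  dem <- single_pop_demography(50, 10)
  gen <- unlinked_genome(500)
  ratios <- vapply(1:20, function(s) {
    sim <- simulate_reintroduction(dem, gen, seed = s)
    p0 <- sim$stages$pop$freq_founding
    pt <- sim$stages$pop$freq_final
    mean(2 * pt * (1 - pt)) / mean(2 * p0 * (1 - p0))
  }, numeric(1))
  expected <- (1 - 1 / 100)^10
  tol <- max(0.01, 3 * stats::sd(ratios) / sqrt(length(ratios)))
  expect_lt(abs(mean(ratios) - expected), tol)
})

test_that("observation model: identity settings and exact reproducibility", {
  gm <- random_gm(5, n = 8, L = 100, miss = 0)
  obs0 <- observation_params(missing_below_depth = 0L, genotype_error_rate = 0)
  o1 <- apply_rad_observation(gm, obs0, seed = 3)
  expect_identical(o1$genotypes$calls, gm$calls)
  expect_identical(dim(o1$coverage$depth), dim(gm$calls))
  o2 <- apply_rad_observation(gm, obs0, seed = 3)
  expect_identical(o2$coverage$depth, o1$coverage$depth)
})

test_that("missingness fraction matches the negative-binomial CDF oracle", {
  gm <- random_gm(6, n = 50, L = 2000, miss = 0)
  obs <- observation_params(
    mean_depth = 14, depth_dispersion = 3, missing_below_depth = 7L,
    genotype_error_rate = 0, mean_depth_sdlog = 0
  )
  o <- apply_rad_observation(gm, obs, seed = 11)
  q <- pnbinom(6, size = 3, mu = 14)
  frac <- mean(is.na(o$genotypes$calls))
  n_tot <- length(o$genotypes$calls)
  expect_lt(abs(frac - q), 3 * sqrt(q * (1 - q) / n_tot) + 1e-6)
})

test_that("genotype errors flip retained calls at the configured rate", {
  gm <- make_gm(matrix(1L, 40, 200))
  obs <- observation_params(
    missing_below_depth = 0L, genotype_error_rate = 0.2, mean_depth_sdlog = 0
  )
  o <- apply_rad_observation(gm, obs, seed = 4)
  flipped <- mean(o$genotypes$calls != 1L)
  expect_lt(abs(flipped - 0.2), 0.02)
  expect_true(all(o$genotypes$calls %in% c(0L, 1L, 2L)))
})

test_that("called ROH lie almost entirely within true IBD tracts", {
  # error-free observation of a strongly bottlenecked stage
  dem <- demography_model(data.frame(
    id = c("src", "inbred"), parent = c(NA, "src"),
    founders = c(NA, 10L), ne = c(100L, 10L), generations = c(0L, 8L),
    role = c("autochthonous", "secondary")
  ))
  gen <- default_genome(n_chrom = 2L, chrom_length_bp = 5e7)
  sim <- simulate_reintroduction(dem, gen, seed = 42, sample_n = 8,
                                 track_ibd = TRUE)
  segs <- call_roh(sim$stages$inbred$genotypes)
  segs <- segs[segs$length_bp >= 5e6, , drop = FALSE]
  expect_gt(nrow(segs), 0L)
  ibd <- true_ibd_segments(sim, "inbred")
  total <- 0
  inside <- 0
  for (r in seq_len(nrow(segs))) {
    sel <- ibd$individual == segs$individual[r] & ibd$chrom == segs$chrom[r]
    total <- total + segs$length_bp[r]
    inside <- inside + overlap_bp(segs$start[r], segs$end[r],
                                  ibd$start[sel], ibd$end[sel])
  }
  expect_gte(inside / total, 0.8)
})
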