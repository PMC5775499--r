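test_that("genotype_matrix enforces its invariants", {
  expect_s3_class(make_gm(matrix(c(0L, 1L, 2L, NA), 2, 2)), "genotype_matrix")
  expect_error(make_gm(matrix(3L, 1, 1)), "0, 1, 2 or NA")
  expect_error(make_gm(matrix(0L, 2, 2), pos = c(10L, 10L)), "strictly increasing")
  expect_error(
    make_gm(matrix(0L, 2, 3), pos = c(1L, 5L, 2L),
            chrom = c("chr1", "chr2", "chr1")),
    "contiguous"
  )
  gm <- make_gm(matrix(0L, 2, 1))
  gm$individuals <- c("a", "a")
  rownames(gm$calls) <- c("a", "a")
  expect_error(validate_genotype_matrix <- reintropop:::validate_genotype_matrix(gm), "unique")
})

test_that("VCF round trip is the identity, with and without coverage", {
  gm <- make_gm(
    rbind(c(0L, 1L, NA), c(2L, 1L, 0L)),
    pos = c(100L, 250L, 900L),
    chrom_lengths = c(chr1 = 10000L)
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_equal(back$genotypes$calls, gm$calls)
  expect_equal(back$genotypes$sites, gm$sites)
  expect_equal(back$genotypes$individuals, gm$individuals)
  expect_equal(attr(back$genotypes, "chrom_lengths"), c(chr1 = 10000L),
               ignore_attr = TRUE)
  expect_null(back$coverage)

  cov <- coverage_profile(rbind(c(9L, 3L, 0L), c(14L, 20L, 7L)),
                          site_footprint = c(180L, 180L, 90L))
  write_vcf(gm, path, cov = cov)
  back <- read_vcf(path)
  expect_equal(back$genotypes$calls, gm$calls)
  expect_equal(back$coverage$depth, cov$depth, ignore_attr = TRUE)
  expect_equal(back$coverage$site_footprint, cov$site_footprint)
})

test_that("VCF round trip holds on randomly generated matrices (property)", {
  for (seed in 1:12) {
    gm <- random_gm(seed, n = sample(2:6, 1), L = sample(5:40, 1))
    path <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(gm, path)
    back <- read_vcf(path)$genotypes
    expect_equal(back$calls, gm$calls)
    expect_equal(back$sites, gm$sites)
    expect_equal(back$individuals, gm$individuals)
  }
})

test_that("missing, half-missing and phased genotypes are mapped correctly", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t10\t.\tA\tC\t.\t.\t.\tGT\t./.\t0|1",
    "chr1\t20\t.\tG\tT\t.\t.\t.\tGT\t0/.\t1/1"
  ), path)
  gm <- read_vcf(path)$genotypes
  expect_identical(gm$calls[, 1], c(s1 = NA_integer_, s2 = 1L))
  expect_identical(gm$calls[, 2], c(s1 = NA_integer_, s2 = 2L))
})

test_that("malformed VCFs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".vcf")
  base_hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1"
  )
  writeLines(c(base_hdr, "chr1\t10\t.\tA\tC,T\t.\t.\t.\tGT\t0/1"), path)
  expect_error(read_vcf(path), "multiallelic record at chr1:10")
  writeLines(c(base_hdr,
               "chr1\t30\t.\tA\tC\t.\t.\t.\tGT\t0/1",
               "chr1\t10\t.\tA\tC\t.\t.\t.\tGT\t0/1"), path)
  expect_error(read_vcf(path), "not sorted")
  file.create(path)
  expect_error(read_vcf(path), "empty")
  # header-only VCF reads back as an empty-site matrix (round trip of an
  # empty panel)
  gm0 <- make_gm(matrix(integer(0), 2, 0), pos = integer(0), chrom = character(0))
  write_vcf(gm0, path)
  expect_equal(n_sites(read_vcf(path)$genotypes), 0L)
})

test_that("population map reading validates roles, duplicates and shape", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("i1\tgp\tautochthonous", "i2\talbris\tprimary",
               "i3\twh\tsecondary"), path)
  pm <- read_population_map(path)
  expect_length(pm$assignments, 3L)
  expect_identical(unname(pm$roles["albris"]), "primary")

  writeLines(c("i1\tgp\tautochthonous", "i1\talbris\tprimary"), path)
  expect_error(read_population_map(path), "duplicate individual")
  writeLines(c("i1\tgp\tzoo"), path)
  expect_error(read_population_map(path), "unknown role")
  writeLines(c("i1\tgp\tautochthonous", "i2\talbris"), path)
  expect_error(read_population_map(path), "line 2")
  # round trip
  writeLines(c("i1\tgp\tautochthonous", "i2\talbris\tprimary"), path)
  pm <- read_population_map(path)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_population_map(pm, path2)
  expect_equal(read_population_map(path2), pm)
})

test_that("subset is order-preserving, idempotent and commutes for disjoint criteria", {
  gm <- random_gm(99, n = 5, L = 30, n_chrom = 2)
  expect_equal(subset(gm), gm)
  expect_error(subset(gm, individuals = "nope"), "unknown individual")
  g0 <- subset(gm, sites = rep(FALSE, n_sites(gm)))
  expect_equal(n_sites(g0), 0L)
  expect_equal(g0$individuals, gm$individuals)

  chr1_only <- subset(gm, sites = function(s) s$chrom == "chr1")
  # hand enumeration
  expect_equal(chr1_only$sites$pos, gm$sites$pos[gm$sites$chrom == "chr1"])
  expect_equal(chr1_only$calls, gm$calls[, gm$sites$chrom == "chr1"],
               ignore_attr = TRUE)
  # idempotence
  expect_equal(subset(chr1_only, sites = function(s) s$chrom == "chr1"), chr1_only)
  # commutation of disjoint criteria
  a <- subset(subset(gm, individuals = c("i01", "i03")),
              sites = function(s) s$pos > 1000)
  b <- subset(subset(gm, sites = function(s) s$pos > 1000),
              individuals = c("i01", "i03"))
  expect_equal(a, b)
})
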