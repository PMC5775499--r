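# Small fixture builders used across the suite. Everything is generated in
# code; no binary fixtures.

make_gm <- function(calls, pos = NULL, chrom = NULL, chrom_lengths = NULL) {
  calls <- as.matrix(calls)
  L <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  if (is.null(chrom)) chrom <- rep("chr1", L)
  genotype_matrix(
    calls,
    sites = data.frame(chrom = chrom, pos = pos, ref = rep("A", L),
                       alt = rep("C", L), stringsAsFactors = FALSE),
    individuals = sprintf("i%02d", seq_len(nrow(calls))),
    chrom_lengths = chrom_lengths
  )
}

random_gm <- function(seed, n = 6L, L = 40L, miss = 0.1, n_chrom = 2L) {
  set.seed(seed)
  p <- runif(L, 0.1, 0.9)
  calls <- matrix(rbinom(n * L, 2L, rep(p, each = n)), n, L)
  calls[matrix(runif(n * L) < miss, n, L)] <- NA_integer_
  chrom <- sort(rep_len(sprintf("chr%d", seq_len(n_chrom)), L))
  pos <- unlist(lapply(unique(chrom), function(ch) {
    sort(sample.int(1e6, sum(chrom == ch)))
  }))
  make_gm(calls, pos = pos, chrom = chrom)
}

# 6-individual toy with one site of each panel-filter class:
#   s1 monomorphic, s2 singleton (one het), s3 private doubleton (one
#   minor-allele homozygote), s4 polymorphic but 50% missing, s5 ordinary
#   polymorphic (minor allele in two individuals)
toy_panel_gm <- function() {
  calls <- cbind(
    c(0L, 0L, 0L, 0L, 0L, 0L),
    c(1L, 0L, 0L, 0L, 0L, 0L),
    c(2L, 0L, 0L, 0L, 0L, 0L),
    c(1L, 1L, 0L, NA, NA, NA),
    c(1L, 1L, 0L, 0L, 0L, 0L)
  )
  make_gm(calls)
}

single_pop_demography <- function(ne, generations, role = "autochthonous") {
  demography_model(data.frame(
    id = "pop", parent = NA_character_, founders = NA_integer_,
    ne = as.integer(ne), generations = as.integer(generations), role = role,
    stringsAsFactors = FALSE
  ))
}

# scaled-down reintroduction preset used by the directional tests (documented
# scaling: keeps the 50 kb marker spacing, shrinks sizes to fit the test
# budget; the serial-bottleneck structure is preserved)
scaled_demography <- function() {
  default_ibex_demography(
    source_ne = 150L, captive_founders = 30L, captive_generations = 2L,
    n_primary = 2L, primary_founders = 20L, primary_ne = 50L,
    n_secondary = 2L, secondary_founders = 15L, secondary_ne = 25L,
    generations = 10L
  )
}

scaled_genome <- function() {
  default_genome(n_chrom = 3L, chrom_length_bp = 5e7, marker_spacing_bp = 50000L)
}
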