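#' Staged reintroduction demography
#'
#' A directed stage graph describing a serial-founder reintroduction: a single
#' root (source) population and descendant stages, each founded by drawing
#' diploid founder individuals without replacement from its parent and then
#' evolving for a fixed number of non-overlapping Wright-Fisher generations at
#' constant size `ne`. The founding draw itself adds no drift in expectation;
#' the first reproduction round after founding is the first generation of
#' drift at the new size.
#'
#' @param stages data.frame with columns `id`, `parent` (NA for the root),
#'   `founders` (diploid founder count, NA for the root), `ne` (constant
#'   diploid size after founding), `generations` (integer >= 0) and `role`
#'   (one of `r paste(POPULATION_ROLES, collapse = ", ")`).
#' @return An object of class `demography_model`.
#' @export
demography_model <- function(stages) {
  stages <- as.data.frame(stages, stringsAsFactors = FALSE)
  need <- c("id", "parent", "founders", "ne", "generations", "role")
  if (!all(need %in% names(stages))) {
    stop("stages must have columns ", paste(need, collapse = ", "))
  }
  stages$id <- as.character(stages$id)
  stages$parent <- as.character(stages$parent)
  if (anyDuplicated(stages$id)) stop("stage IDs must be unique")
  root <- is.na(stages$parent)
  if (sum(root) != 1L) stop("demography must have exactly one root stage")
  known <- stages$parent[!root] %in% stages$id
  if (!all(known)) {
    stop("unknown parent stage: ", paste(stages$parent[!root][!known], collapse = ", "))
  }
  if (any(stages$ne < 1L)) stop("ne must be >= 1 for every stage")
  if (any(stages$generations < 0L)) stop("generations must be >= 0")
  bad_role <- setdiff(stages$role, POPULATION_ROLES)
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  # topological order (also proves acyclicity)
  ord <- character(0)
  remaining <- stages$id
  placed <- stages$id[root]
  ord <- placed
  remaining <- setdiff(remaining, placed)
  while (length(remaining)) {
    ready <- remaining[stages$parent[match(remaining, stages$id)] %in% ord]
    if (!length(ready)) stop("demography stage graph contains a cycle")
    ord <- c(ord, ready)
    remaining <- setdiff(remaining, ready)
  }
  pid <- match(stages$parent, stages$id)
  fb <- !root & stages$founders > stages$ne[pid]
  if (any(fb, na.rm = TRUE)) {
    stop(
      "founder count exceeds parent Ne for stage(s): ",
      paste(stages$id[which(fb)], collapse = ", ")
    )
  }
  structure(
    list(stages = stages, order = ord),
    class = "demography_model"
  )
}

#' @export
print.demography_model <- function(x, ...) {
  cat("demography_model with", nrow(x$stages), "stage(s):\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Default Alpine ibex reintroduction demography
#'
#' Preset mirroring the documented reintroduction history: a large
#' autochthonous source population (Ne ~ 1000), a captive breeding stock of
#' 88 founders, three primary reintroduced populations (Ne 300) and three
#' secondary populations (Ne 80), each secondary founded from a single
#' primary, with 10 generations of isolated drift after each founding.
#' All parameters can be overridden.
#'
#' @param source_ne diploid size of the source population.
#' @param captive_founders founders drawn from the source into captivity.
#' @param captive_generations generations of captive breeding.
#' @param n_primary,primary_founders,primary_ne primary-stage parameters.
#' @param n_secondary,secondary_founders,secondary_ne secondary-stage
#'   parameters; secondary stage i is founded from primary
#'   `((i - 1) %% n_primary) + 1`.
#' @param generations generations of isolated drift after each reintroduction.
#' @return a [demography_model()].
#' @export
default_ibex_demography <- function(source_ne = 1000L,
                                    captive_founders = 88L,
                                    captive_generations = 2L,
                                    n_primary = 3L,
                                    primary_founders = 30L,
                                    primary_ne = 300L,
                                    n_secondary = 3L,
                                    secondary_founders = 20L,
                                    secondary_ne = 80L,
                                    generations = 10L) {
  rows <- list(
    data.frame(
      id = "source", parent = NA_character_, founders = NA_integer_,
      ne = source_ne, generations = 0L, role = "autochthonous",
      stringsAsFactors = FALSE
    ),
    data.frame(
      id = "captive", parent = "source", founders = captive_founders,
      ne = captive_founders, generations = captive_generations,
      role = "captive", stringsAsFactors = FALSE
    )
  )
  for (i in seq_len(n_primary)) {
    rows <- c(rows, list(data.frame(
      id = sprintf("primary%d", i), parent = "captive",
      founders = primary_founders, ne = primary_ne,
      generations = generations, role = "primary", stringsAsFactors = FALSE
    )))
  }
  for (i in seq_len(n_secondary)) {
    rows <- c(rows, list(data.frame(
      id = sprintf("secondary%d", i),
      parent = sprintf("primary%d", ((i - 1L) %% n_primary) + 1L),
      founders = secondary_founders, ne = secondary_ne,
      generations = generations, role = "secondary", stringsAsFactors = FALSE
    )))
  }
  demography_model(do.call(rbind, rows))
}

#' Marker map for the simulated genome
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param marker_spacing_bp uniform marker spacing in bp (markers at
#'   `spacing, 2*spacing, ...`); ignored when `positions` is given.
#' @param positions optional named list of sorted marker positions per
#'   chromosome.
#' @param recombination_cm_per_mb uniform recombination rate (cM/Mb).
#' @param unlinked if TRUE, every marker segregates independently (free
#'   recombination); chromosome labels are retained for bookkeeping only.
#' @return An object of class `genome_map`.
#' @export
genome_map <- function(chrom_lengths, marker_spacing_bp = 50000L,
                       positions = NULL, recombination_cm_per_mb = 1,
                       unlinked = FALSE) {
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- sprintf("chr%d", seq_along(chrom_lengths))
  }
  chrom_lengths <- vapply(chrom_lengths, as.integer, integer(1))
  if (is.null(positions)) {
    positions <- lapply(chrom_lengths, function(len) {
      as.integer(seq.int(marker_spacing_bp, len, by = marker_spacing_bp))
    })
  }
  positions <- positions[names(chrom_lengths)]
  for (chr in names(positions)) {
    p <- positions[[chr]]
    if (!length(p)) stop("chromosome ", chr, " has no markers")
    if (any(p < 1L) || any(p > chrom_lengths[[chr]])) {
      stop("marker positions outside [1, length] on ", chr)
    }
    if (any(diff(p) <= 0L)) stop("marker positions not strictly increasing on ", chr)
  }
  if (recombination_cm_per_mb <= 0) stop("recombination rate must be > 0")
  structure(
    list(
      chrom_lengths = chrom_lengths,
      positions = positions,
      recombination_cm_per_mb = recombination_cm_per_mb,
      unlinked = unlinked
    ),
    class = "genome_map"
  )
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf(
    "genome_map: %d chromosome(s), %d markers, %.2f cM/Mb%s\n",
    length(x$chrom_lengths), sum(lengths(x$positions)),
    x$recombination_cm_per_mb, if (x$unlinked) " (unlinked)" else ""
  ))
  invisible(x)
}

#' Desk-scale default genome: 5 chromosomes x 100 Mb, one marker per 50 kb
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param marker_spacing_bp marker spacing in bp.
#' @param recombination_cm_per_mb recombination rate.
#' @return a [genome_map()].
#' @export
default_genome <- function(n_chrom = 5L, chrom_length_bp = 1e8,
                           marker_spacing_bp = 50000L,
                           recombination_cm_per_mb = 1) {
  genome_map(
    stats::setNames(rep(as.integer(chrom_length_bp), n_chrom),
                    sprintf("chr%d", seq_len(n_chrom))),
    marker_spacing_bp = marker_spacing_bp,
    recombination_cm_per_mb = recombination_cm_per_mb
  )
}

#' Genome of fully unlinked loci
#'
#' Convenience map for drift experiments where loci must be independent.
#' Loci are spread over `n_chrom` bookkeeping chromosomes (1 Mb apart) but
#' segregate freely regardless of position.
#'
#' @param n_loci number of loci.
#' @param n_chrom number of bookkeeping chromosomes.
#' @return a [genome_map()] with `unlinked = TRUE`.
#' @export
unlinked_genome <- function(n_loci, n_chrom = 25L) {
  per <- diff(floor(seq(0, n_loci, length.out = n_chrom + 1L)))
  per <- per[per > 0L]
  positions <- lapply(per, function(k) as.integer(1e6 * seq_len(k)))
  names(positions) <- sprintf("chrU%02d", seq_along(positions))
  lens <- vapply(positions, function(p) p[length(p)] + 1L, integer(1))
  genome_map(lens, positions = positions, unlinked = TRUE)
}

with_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory (reproducibility)")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer(seed))
  force(code)
}

# Crossover mask for n_off gametes: entry 0 means the allele comes from the
# parent's first haplotype, 1 from the second. Haldane model: crossover count
# per chromosome is Poisson with mean = genetic length in Morgans, crossover
# positions uniform on the physical map (rate is uniform in cM/Mb).
crossover_masks <- function(n_off, genome) {
  L <- sum(lengths(genome$positions))
  if (genome$unlinked) {
    return(matrix(sample.int(2L, n_off * L, replace = TRUE) - 1L, n_off, L))
  }
  M <- matrix(0L, n_off, L)
  offset <- 0L
  for (chr in names(genome$positions)) {
    pos <- genome$positions[[chr]]
    nc <- length(pos)
    len <- genome$chrom_lengths[[chr]]
    morgans <- genome$recombination_cm_per_mb * (len / 1e6) / 100
    k <- stats::rpois(n_off, morgans)
    start <- sample.int(2L, n_off, replace = TRUE) - 1L
    plain <- k == 0L
    if (any(plain)) {
      M[plain, offset + seq_len(nc)] <- start[plain]
    }
    for (i in which(!plain)) {
      breaks <- sort(stats::runif(k[i], 0, len))
      M[i, offset + seq_len(nc)] <-
        (start[i] + findInterval(pos, breaks)) %% 2L
    }
    offset <- offset + nc
  }
  M
}

# One gamete per row of parent_idx, drawn from state matrices h1/h2 (and the
# ancestry matrices a1/a2 when IBD is being tracked).
make_gametes <- function(state, parent_idx, genome, track_ibd) {
  M <- crossover_masks(length(parent_idx), genome)
  take2 <- M == 1L
  h <- state$h1[parent_idx, , drop = FALSE]
  h2 <- state$h2[parent_idx, , drop = FALSE]
  h[take2] <- h2[take2]
  out <- list(h = h)
  if (track_ibd) {
    a <- state$a1[parent_idx, , drop = FALSE]
    a2 <- state$a2[parent_idx, , drop = FALSE]
    a[take2] <- a2[take2]
    out$a <- a
  }
  out
}

evolve_stage <- function(state, ne, generations, genome, track_ibd) {
  for (g in seq_len(generations)) {
    n_par <- nrow(state$h1)
    if (n_par < 2L) stop("cannot reproduce: fewer than 2 parents")
    par1 <- sample.int(n_par, ne, replace = TRUE)
    par2 <- sample.int(n_par, ne, replace = TRUE)
    repeat {
      clash <- par2 == par1
      if (!any(clash)) break
      par2[clash] <- sample.int(n_par, sum(clash), replace = TRUE)
    }
    g1 <- make_gametes(state, par1, genome, track_ibd)
    g2 <- make_gametes(state, par2, genome, track_ibd)
    state <- list(h1 = g1$h, h2 = g2$h, a1 = g1$a, a2 = g2$a)
  }
  state
}

#' Forward Wright-Fisher simulation of a staged reintroduction
#'
#' Simulates standing variation (no new mutation) at the markers of `genome`
#' through the stage graph of `demography`: diploid individuals, monoecious
#' random mating with two distinct parents, non-overlapping generations,
#' recombination under the Haldane model. The root stage is initialised at
#' linkage equilibrium from `init_freq`.
#'
#' @param demography a [demography_model()].
#' @param genome a [genome_map()].
#' @param init_freq either a length-2 numeric range (initial allele
#'   frequencies drawn uniformly from it), a numeric vector with one frequency
#'   per marker, or a `function(n_loci)` returning such a vector.
#' @param seed mandatory integer seed.
#' @param sample_n if given, only this many individuals per stage are retained
#'   in the per-stage genotype matrices (drawn without replacement); whole
#'   stages are kept otherwise.
#' @param track_ibd if TRUE, founder-haplotype ancestry is propagated so that
#'   true autozygous (IBD) tracts can be recovered with
#'   [true_ibd_segments()].
#' @return An object of class `reintro_sim`: a list with per-stage results
#'   (`genotypes`, whole-population allele frequencies at founding and at the
#'   end, optional ancestry matrices), the population map of the sampled
#'   individuals, and the inputs.
#' @export
simulate_reintroduction <- function(demography, genome,
                                    init_freq = c(0.05, 0.95),
                                    seed, sample_n = NULL,
                                    track_ibd = FALSE) {
  stopifnot(inherits(demography, "demography_model"), inherits(genome, "genome_map"))
  L <- sum(lengths(genome$positions))
  with_seed(seed, {
    p0 <- if (is.function(init_freq)) {
      init_freq(L)
    } else if (length(init_freq) == 2L && L != 2L) {
      stats::runif(L, init_freq[1L], init_freq[2L])
    } else if (length(init_freq) == L) {
      as.numeric(init_freq)
    } else {
      stop("init_freq must be a range, a per-marker vector, or a function")
    }
    if (any(p0 < 0 | p0 > 1)) stop("initial frequencies must be in [0, 1]")

    sites <- data.frame(
      chrom = rep(names(genome$positions), lengths(genome$positions)),
      pos = unlist(genome$positions, use.names = FALSE),
      ref = "A", alt = "C", stringsAsFactors = FALSE
    )
    st <- demography$stages
    states <- list()
    out <- list()
    for (id in demography$order) {
      row <- st[st$id == id, ]
      if (is.na(row$parent)) {
        n0 <- row$ne
        h1 <- matrix(stats::rbinom(n0 * L, 1L, rep(p0, each = n0)), n0, L)
        h2 <- matrix(stats::rbinom(n0 * L, 1L, rep(p0, each = n0)), n0, L)
        state <- list(h1 = h1, h2 = h2)
        if (track_ibd) {
          state$a1 <- matrix(rep(seq_len(n0) * 2L - 1L, L), n0, L)
          state$a2 <- matrix(rep(seq_len(n0) * 2L, L), n0, L)
        }
      } else {
        parent_state <- states[[row$parent]]
        n_par <- nrow(parent_state$h1)
        if (row$founders > n_par) {
          stop(sprintf(
            "stage %s: founder count %d exceeds parent size %d",
            id, row$founders, n_par
          ))
        }
        idx <- sample.int(n_par, row$founders, replace = FALSE)
        state <- list(
          h1 = parent_state$h1[idx, , drop = FALSE],
          h2 = parent_state$h2[idx, , drop = FALSE]
        )
        if (track_ibd) {
          state$a1 <- parent_state$a1[idx, , drop = FALSE]
          state$a2 <- parent_state$a2[idx, , drop = FALSE]
        }
      }
      freq_founding <- colMeans(state$h1 + state$h2) / 2
      state <- evolve_stage(state, row$ne, row$generations, genome, track_ibd)
      freq_final <- colMeans(state$h1 + state$h2) / 2
      states[[id]] <- state

      n_now <- nrow(state$h1)
      keep <- if (is.null(sample_n)) {
        seq_len(n_now)
      } else {
        sort(sample.int(n_now, min(sample_n, n_now)))
      }
      gm <- genotype_matrix(
        calls = state$h1[keep, , drop = FALSE] + state$h2[keep, , drop = FALSE],
        sites = sites,
        individuals = sprintf("%s_%03d", id, keep),
        chrom_lengths = genome$chrom_lengths
      )
      out[[id]] <- list(
        genotypes = gm,
        freq_founding = freq_founding,
        freq_final = freq_final,
        ibd = if (track_ibd) {
          list(
            a1 = state$a1[keep, , drop = FALSE],
            a2 = state$a2[keep, , drop = FALSE]
          )
        }
      )
    }
    assignments <- stats::setNames(
      unlist(lapply(names(out), function(id) out[[id]]$genotypes$individuals)),
      NULL
    )
    pops <- rep(names(out), vapply(out, function(s) n_ind(s$genotypes), integer(1)))
    popmap <- population_map(
      stats::setNames(pops, assignments),
      stats::setNames(st$role, st$id)
    )
    structure(
      list(
        stages = out, popmap = popmap, demography = demography,
        genome = genome, seed = seed, init_freq = p0
      ),
      class = "reintro_sim"
    )
  })
}

#' @export
print.reintro_sim <- function(x, ...) {
  cat(sprintf(
    "reintro_sim: %d stage(s), %d markers, seed %d\n",
    length(x$stages), length(x$init_freq), x$seed
  ))
  for (id in names(x$stages)) {
    cat(sprintf("  %-12s %3d individuals retained\n", id,
                n_ind(x$stages[[id]]$genotypes)))
  }
  invisible(x)
}

#' Stack all sampled stage genotypes into one genotype matrix
#' @param sim a `reintro_sim`.
#' @return a [genotype_matrix()] with all retained individuals.
#' @export
combined_genotypes <- function(sim) {
  stopifnot(inherits(sim, "reintro_sim"))
  calls <- do.call(rbind, lapply(sim$stages, function(s) s$genotypes$calls))
  first <- sim$stages[[1L]]$genotypes
  genotype_matrix(
    calls = calls,
    sites = first$sites,
    individuals = unlist(lapply(sim$stages, function(s) s$genotypes$individuals),
                         use.names = FALSE),
    chrom_lengths = attr(first, "chrom_lengths")
  )
}

#' True autozygous (IBD) tracts from simulated ancestry
#'
#' Maximal runs of markers at which an individual's two haplotypes descend
#' from the same root-stage founder haplotype. Requires
#' `simulate_reintroduction(..., track_ibd = TRUE)`.
#'
#' @param sim a `reintro_sim` with IBD tracking.
#' @param stage stage ID.
#' @return data.frame with columns individual, chrom, start, end, n_markers.
#' @export
true_ibd_segments <- function(sim, stage) {
  s <- sim$stages[[stage]]
  if (is.null(s)) stop("unknown stage: ", stage)
  if (is.null(s$ibd)) stop("simulation was run without track_ibd = TRUE")
  gm <- s$genotypes
  res <- list()
  for (i in seq_len(n_ind(gm))) {
    auto <- s$ibd$a1[i, ] == s$ibd$a2[i, ]
    for (chr in unique(gm$sites$chrom)) {
      sel <- gm$sites$chrom == chr
      a <- auto[sel]
      pos <- gm$sites$pos[sel]
      r <- rle(a)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        res[[length(res) + 1L]] <- data.frame(
          individual = gm$individuals[i], chrom = chr,
          start = pos[starts[j]], end = pos[ends[j]],
          n_markers = r$lengths[j], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(res)) {
    return(data.frame(
      individual = character(0), chrom = character(0),
      start = integer(0), end = integer(0), n_markers = integer(0)
    ))
  }
  do.call(rbind, res)
}

#' RAD-seq-like observation model parameters
#'
#' Sequencing depth per genotype is negative-binomial around a per-individual
#' mean; individual means vary lognormally to emulate uneven coverage among
#' barcoded libraries. Calls below `missing_below_depth` reads are set
#' missing; retained calls are perturbed with probability
#' `genotype_error_rate` (a heterozygote becomes a random homozygote and vice
#' versa).
#'
#' @param mean_depth expected read depth (scalar, or one value per
#'   individual in which case `mean_depth_sdlog` is ignored).
#' @param depth_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param missing_below_depth depth threshold below which a call is missing.
#' @param genotype_error_rate per-retained-call error probability.
#' @param mean_depth_sdlog lognormal sdlog of among-individual depth variation.
#' @param site_footprint bp of sequence each site represents.
#' @return An object of class `observation_params`.
#' @export
observation_params <- function(mean_depth = 14, depth_dispersion = 3,
                               missing_below_depth = 7L,
                               genotype_error_rate = 0.001,
                               mean_depth_sdlog = 0.3,
                               site_footprint = 180L) {
  stopifnot(
    all(mean_depth >= 0), depth_dispersion > 0,
    missing_below_depth >= 0,
    genotype_error_rate >= 0, genotype_error_rate <= 1,
    mean_depth_sdlog >= 0, site_footprint > 0
  )
  structure(
    list(
      mean_depth = mean_depth, depth_dispersion = depth_dispersion,
      missing_below_depth = as.integer(missing_below_depth),
      genotype_error_rate = genotype_error_rate,
      mean_depth_sdlog = mean_depth_sdlog,
      site_footprint = as.integer(site_footprint)
    ),
    class = "observation_params"
  )
}

#' Apply the RAD-seq observation model to true genotypes
#'
#' @param gm a [genotype_matrix()] of true genotypes.
#' @param obs an [observation_params()].
#' @param seed mandatory integer seed.
#' @return list with `genotypes` (observed, with missingness and errors) and
#'   `coverage` (a [coverage_profile()]).
#' @export
apply_rad_observation <- function(gm, obs, seed) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(obs, "observation_params"))
  n <- n_ind(gm)
  L <- n_sites(gm)
  with_seed(seed, {
    mu <- if (length(obs$mean_depth) == n) {
      as.numeric(obs$mean_depth)
    } else if (obs$mean_depth_sdlog > 0) {
      stats::rlnorm(n,
        meanlog = log(obs$mean_depth) - obs$mean_depth_sdlog^2 / 2,
        sdlog = obs$mean_depth_sdlog
      )
    } else {
      rep(obs$mean_depth, n)
    }
    depth <- matrix(
      stats::rnbinom(n * L, size = obs$depth_dispersion, mu = mu),
      n, L
    )
    calls <- gm$calls
    calls[depth < obs$missing_below_depth] <- NA_integer_
    if (obs$genotype_error_rate > 0) {
      err <- matrix(stats::runif(n * L) < obs$genotype_error_rate, n, L)
      err[is.na(calls)] <- FALSE
      het_err <- which(err & calls == 1L)
      hom_err <- which(err & calls != 1L)
      if (length(het_err)) {
        calls[het_err] <- 2L * stats::rbinom(length(het_err), 1L, 0.5)
      }
      if (length(hom_err)) calls[hom_err] <- 1L
    }
    list(
      genotypes = genotype_matrix(
        calls, gm$sites,
        individuals = gm$individuals,
        chrom_lengths = attr(gm, "chrom_lengths")
      ),
      coverage = coverage_profile(depth, site_footprint = obs$site_footprint)
    )
  })
}
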