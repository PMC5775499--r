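default_run_config <- function() {
  list(
    mode = "simulate",
    seed = NULL,
    vcf = NULL,
    popmap = NULL,
    sample_n = 15L,
    panel = "general",
    demography = list(
      source_ne = 1000L, captive_founders = 88L, captive_generations = 2L,
      n_primary = 3L, primary_founders = 30L, primary_ne = 300L,
      n_secondary = 3L, secondary_founders = 20L, secondary_ne = 80L,
      generations = 10L
    ),
    genome = list(
      n_chrom = 5L, chrom_length_bp = 1e8, marker_spacing_bp = 50000L,
      recombination_cm_per_mb = 1
    ),
    observation = list(
      mean_depth = 14, depth_dispersion = 3, missing_below_depth = 7L,
      genotype_error_rate = 0.001, mean_depth_sdlog = 0.3,
      site_footprint = 180L
    ),
    roh = list(
      window_snp = 25L, window_het_max = 1L, window_missing_max = 5L,
      window_hit_threshold = 0.05, segment_snp_min = 25L,
      segment_kb_min = 1000, segment_het_max = 1L,
      density_min_kb_per_snp = 50, gap_max_kb = 1000, froh_min_mb = 10
    ),
    ne = list(maf_min = 0.1, min_distance_bp = 250000, mating = "random"),
    resampling = list(enabled = TRUE, reps = 100L)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section is not a mapping at ", path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key: ", sub("^/", "", paste0(path, "/", unknown[1L])))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(defaults[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, "/", k))
    } else {
      v <- user[[k]]
      if (!is.null(defaults[[k]]) && is.numeric(defaults[[k]]) &&
          !is.numeric(v)) {
        stop("config key ", sub("^/", "", paste0(path, "/", k)),
             " must be numeric")
      }
      defaults[[k]] <- v
    }
  }
  defaults
}

#' Validate and complete a pipeline run configuration
#'
#' Accepts a YAML or JSON file path, or an R list, merges it over the package
#' defaults (preset demography, the ROH parameterization, the LD-Ne settings)
#' and rejects unknown keys with the offending key path. A master seed is
#' mandatory in simulate mode; in analyze mode the referenced VCF and
#' population-map files must exist.
#'
#' @param config path to a config file, an R list of overrides, or `NULL`
#'   (pure defaults; still needs `seed` for simulate mode).
#' @return a validated config list of class `run_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- merge_config(default_run_config(), config)
  if (!cfg$mode %in% c("simulate", "analyze-vcf")) {
    stop("mode must be 'simulate' or 'analyze-vcf'")
  }
  if (cfg$mode == "simulate") {
    if (is.null(cfg$seed)) stop("a master seed is mandatory in simulate mode")
  } else {
    if (is.null(cfg$vcf) || !file.exists(cfg$vcf)) {
      stop("analyze-vcf mode requires an existing 'vcf' path")
    }
    if (is.null(cfg$popmap) || !file.exists(cfg$popmap)) {
      stop("analyze-vcf mode requires an existing 'popmap' path")
    }
    if (is.null(cfg$seed)) cfg$seed <- 1L
  }
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$panel %in% c("general", "multispecies", "intraspecies")) {
    stop("panel must be one of general, multispecies, intraspecies")
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage_log <- function(manifest, stage, ...) {
  line <- sprintf("[%s] %s", stage, paste0(...))
  message(line)
  c(manifest, line)
}

#' Run the full simulate/observe/filter/analyze pipeline
#'
#' In simulate mode: forward-simulates the configured reintroduction
#' demography, applies the RAD observation model, writes VCF and population
#' map, then runs the analysis stages. In analyze-vcf mode the genotypes and
#' population map are read from the configured files. Outputs (all under
#' `out_dir`): `simulated.vcf` + `popmap.tsv` (simulate mode),
#' `diversity.tsv`, `resampling.tsv`, `fst_matrix.tsv`, `roh_segments.bed`,
#' `roh_profiles.tsv`, `ne.tsv`, and `manifest.json` with all seeds and
#' parameters. Identical config and seed give byte-identical tables.
#'
#' @param config a [validate_config()] result, or anything it accepts.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  seeds <- list(
    simulate = cfg$seed + 1L, observe = cfg$seed + 2L,
    resample = cfg$seed + 3L
  )

  if (cfg$mode == "simulate") {
    dem <- do.call(default_ibex_demography, cfg$demography)
    gen <- default_genome(
      n_chrom = cfg$genome$n_chrom,
      chrom_length_bp = cfg$genome$chrom_length_bp,
      marker_spacing_bp = cfg$genome$marker_spacing_bp,
      recombination_cm_per_mb = cfg$genome$recombination_cm_per_mb
    )
    log <- stage_log(log, "simulate", sprintf(
      "%d stages, %d markers, seed %d",
      nrow(dem$stages), sum(lengths(gen$positions)), seeds$simulate
    ))
    sim <- simulate_reintroduction(dem, gen,
      seed = seeds$simulate, sample_n = cfg$sample_n
    )
    gm_true <- combined_genotypes(sim)
    popmap <- sim$popmap
    obs <- do.call(observation_params, cfg$observation)
    observed <- apply_rad_observation(gm_true, obs, seed = seeds$observe)
    gm <- observed$genotypes
    cov <- observed$coverage
    log <- stage_log(log, "observe", sprintf(
      "missingness %.1f%%", 100 * mean(is.na(gm$calls))
    ))
    write_vcf(gm, file.path(out_dir, "simulated.vcf"), cov = cov)
    write_population_map(popmap, file.path(out_dir, "popmap.tsv"))
  } else {
    res <- read_vcf(cfg$vcf)
    gm <- res$genotypes
    cov <- res$coverage
    popmap <- read_population_map(cfg$popmap)
    log <- stage_log(log, "read", sprintf(
      "%d individuals x %d sites from %s", n_ind(gm), n_sites(gm), cfg$vcf
    ))
  }

  # panel construction
  spec <- panel_preset(cfg$panel)
  groups <- popmap
  panel <- build_panel(gm, groups, spec)
  if (!is.null(cov)) {
    cov_panel <- coverage_profile(
      cov$depth[, match_sites(gm, panel), drop = FALSE],
      cov$site_footprint[match_sites(gm, panel)]
    )
    n_before <- n_sites(panel)
    panel2 <- coverage_paralog_filter(panel, cov_panel)
    cov_panel <- coverage_profile(
      cov_panel$depth[, match_sites(panel, panel2), drop = FALSE],
      cov_panel$site_footprint[match_sites(panel, panel2)]
    )
    panel <- panel2
    log <- stage_log(log, "panel", sprintf(
      "%s: %d sites (paralog filter removed %d)",
      cfg$panel, n_sites(panel), n_before - n_sites(panel)
    ))
  } else {
    cov_panel <- NULL
    log <- stage_log(log, "panel", sprintf("%s: %d sites", cfg$panel, n_sites(panel)))
  }

  results <- list(panel = panel, popmap = popmap)

  if (!is.null(cov_panel)) {
    div <- diversity_table(panel, cov_panel, popmap)
    write_tsv(div, file.path(out_dir, "diversity.tsv"))
    results$diversity <- div
    log <- stage_log(log, "diversity", sprintf("%d populations", nrow(div)))
    if (isTRUE(cfg$resampling$enabled)) {
      curves <- list()
      for (pop in unique(popmap$assignments)) {
        inds <- population_individuals(popmap, pop)
        if (length(inds) >= 2L) {
          cur <- resample_snp_density(panel, cov_panel, inds,
            reps = cfg$resampling$reps, seed = seeds$resample
          )
          cur <- cbind(group = pop, cur)
          curves[[pop]] <- cur
        }
      }
      curves <- do.call(rbind, curves)
      rownames(curves) <- NULL
      write_tsv(curves, file.path(out_dir, "resampling.tsv"))
      results$resampling <- curves
      log <- stage_log(log, "resampling", sprintf(
        "%d replicates", if (is.null(curves)) 0L else nrow(curves)
      ))
    }
  }

  pops <- unique(popmap$assignments)
  if (length(pops) >= 2L) {
    fst <- matrix(NA_real_, length(pops), length(pops),
                  dimnames = list(pops, pops))
    for (i in seq_along(pops)) {
      for (j in seq_along(pops)) {
        if (j <= i) next
        fst[i, j] <- fst[j, i] <- tryCatch(
          pairwise_fst(panel,
            population_individuals(popmap, pops[i]),
            population_individuals(popmap, pops[j])
          ),
          error = function(e) NA_real_
        )
      }
    }
    diag(fst) <- 0
    write_tsv(cbind(population = rownames(fst), as.data.frame(fst)),
              file.path(out_dir, "fst_matrix.tsv"))
    results$fst <- fst
    log <- stage_log(log, "fst", sprintf("%d x %d matrix", nrow(fst), ncol(fst)))
  }

  rparams <- do.call(roh_params, cfg$roh)
  segs <- call_roh(panel, rparams)
  auto_len <- autosome_length(panel)
  profiles <- roh_profiles(segs, auto_len,
    individuals = panel$individuals, froh_min_mb = rparams$froh_min_mb
  )
  write_roh_bed(segs, file.path(out_dir, "roh_segments.bed"))
  write_tsv(profiles, file.path(out_dir, "roh_profiles.tsv"))
  results$roh <- list(segments = segs, profiles = profiles)
  log <- stage_log(log, "roh", sprintf(
    "%d segments over %d individuals", nrow(segs), n_ind(panel)
  ))

  ne_rows <- list()
  for (pop in pops) {
    inds <- population_individuals(popmap, pop)
    est <- tryCatch(
      ne_from_ld(panel, inds,
        maf_min = cfg$ne$maf_min,
        min_distance_bp = cfg$ne$min_distance_bp, mating = cfg$ne$mating
      ),
      error = function(e) NULL
    )
    if (!is.null(est)) {
      ne_rows[[pop]] <- data.frame(
        population = pop, method = "ld", ne = est$estimate,
        ci_lower = est$ci_lower, ci_upper = est$ci_upper,
        maf_min = cfg$ne$maf_min, stringsAsFactors = FALSE
      )
    }
  }
  ne_tab <- if (length(ne_rows)) do.call(rbind, ne_rows) else
    data.frame(population = character(0), method = character(0),
               ne = numeric(0), ci_lower = numeric(0), ci_upper = numeric(0),
               maf_min = numeric(0))
  rownames(ne_tab) <- NULL
  write_tsv(ne_tab, file.path(out_dir, "ne.tsv"))
  results$ne <- ne_tab
  log <- stage_log(log, "ne", sprintf("%d population estimate(s)", nrow(ne_tab)))

  manifest <- list(
    package = "reintropop",
    version = as.character(utils::packageVersion("reintropop")),
    mode = cfg$mode, master_seed = cfg$seed, stage_seeds = seeds,
    config = unclass(cfg), log = log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  invisible(results)
}

# index of gm_sub's sites within gm (both subsets of the same site table)
match_sites <- function(gm, gm_sub) {
  key <- paste(gm$sites$chrom, gm$sites$pos)
  match(paste(gm_sub$sites$chrom, gm_sub$sites$pos), key)
}

# total autosomal length: contig headers when available, else the span of
# the observed markers
autosome_length <- function(gm) {
  cl <- attr(gm, "chrom_lengths")
  if (!is.null(cl)) return(sum(as.numeric(cl)))
  sum(vapply(unique(gm$sites$chrom), function(chr) {
    as.numeric(max(gm$sites$pos[gm$sites$chrom == chr]))
  }, numeric(1)))
}

#' Command-line entry point
#'
#' Implements `reintropop simulate --config run.yaml --seed 1 --out DIR` and
#' `reintropop analyze --vcf file.vcf --popmap map.tsv [--config run.yaml]
#' --out DIR` (the `roh`, `ne` and `diversity` subcommands run the analyze
#' pipeline and simply point at the relevant output table).
#'
#' @param args character vector of CLI arguments.
#' @return exit status, invisibly.
#' @export
reintropop_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: reintropop <simulate|analyze|roh|ne|diversity>",
    "[--config FILE] [--vcf FILE] [--popmap FILE] [--seed INT] --out DIR"
  )
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1L]
  opts <- list()
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--") || i == length(rest)) {
      stop("malformed argument: ", rest[i])
    }
    opts[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  if (is.null(opts$out)) stop("--out is required\n", usage)
  overrides <- if (!is.null(opts$config)) validate_config(opts$config) else NULL
  cfg <- if (is.null(overrides)) default_run_config() else unclass(overrides)
  if (cmd == "simulate") {
    cfg$mode <- "simulate"
  } else if (cmd %in% c("analyze", "roh", "ne", "diversity")) {
    cfg$mode <- "analyze-vcf"
    if (!is.null(opts$vcf)) cfg$vcf <- opts$vcf
    if (!is.null(opts$popmap)) cfg$popmap <- opts$popmap
  } else {
    stop("unknown subcommand: ", cmd, "\n", usage)
  }
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  run_pipeline(validate_config(cfg), opts$out)
  invisible(0L)
}
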