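#' Parameters of the windowed ROH caller
#'
#' Defaults replicate the plink `--homozyg` parameterization used for the
#' ibex RAD panel: 25-SNP sliding windows allowing at most 1 heterozygous and
#' 5 missing calls, a 5% window-hit threshold per SNP, and segments of at
#' least 25 SNPs spanning >= 1,000 kb with at most 1 heterozygous call, a
#' density of at least one SNP per 50 kb, and no neighbouring-SNP gap above
#' 1,000 kb. `froh_min_mb` is the tract-length threshold entering the F_ROH
#' inbreeding coefficient.
#'
#' @param window_snp window size in SNPs.
#' @param window_het_max maximum heterozygous calls per homozygous window.
#' @param window_missing_max maximum missing calls per homozygous window.
#' @param window_hit_threshold minimum proportion of homozygous windows
#'   containing a SNP for that SNP to lie in a homozygous segment.
#' @param segment_snp_min minimum SNPs per emitted segment.
#' @param segment_kb_min minimum segment span in kb.
#' @param segment_het_max maximum heterozygous calls per segment.
#' @param density_min_kb_per_snp maximum kb of span per SNP (density floor).
#' @param gap_max_kb maximum gap between neighbouring SNPs in kb.
#' @param froh_min_mb minimum tract length (Mb) entering F_ROH.
#' @return An object of class `roh_params`.
#' @export
roh_params <- function(window_snp = 25L, window_het_max = 1L,
                       window_missing_max = 5L, window_hit_threshold = 0.05,
                       segment_snp_min = 25L, segment_kb_min = 1000,
                       segment_het_max = 1L, density_min_kb_per_snp = 50,
                       gap_max_kb = 1000, froh_min_mb = 10) {
  stopifnot(
    window_snp >= 1L, window_het_max >= 0L, window_missing_max >= 0L,
    window_hit_threshold > 0, window_hit_threshold <= 1,
    segment_snp_min >= 1L, segment_kb_min > 0, segment_het_max >= 0L,
    density_min_kb_per_snp > 0, gap_max_kb > 0, froh_min_mb > 0
  )
  structure(
    list(
      window_snp = as.integer(window_snp),
      window_het_max = as.integer(window_het_max),
      window_missing_max = as.integer(window_missing_max),
      window_hit_threshold = window_hit_threshold,
      segment_snp_min = as.integer(segment_snp_min),
      segment_kb_min = segment_kb_min,
      segment_het_max = as.integer(segment_het_max),
      density_min_kb_per_snp = density_min_kb_per_snp,
      gap_max_kb = gap_max_kb,
      froh_min_mb = froh_min_mb
    ),
    class = "roh_params"
  )
}

running_sum <- function(x, w) {
  cs <- cumsum(c(0L, x))
  cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]
}

# Core scan of one individual's calls on one chromosome. Three stages:
# (1) score every full window homozygous/not; (2) flag each SNP by the
# proportion of its covering windows that scored homozygous (each SNP's own
# window count: edge SNPs belong to fewer windows); (3) split maximal flagged
# runs at oversized gaps, then emit runs meeting the SNP-count, span, het,
# and density criteria. Segment length is end - start + 1 (inclusive bp).
# Stage 1+2: which SNPs lie in a homozygous segment. Monotone in the het
# calls: turning a heterozygote homozygous can only add flagged SNPs.
roh_flags <- function(calls, params) {
  n <- length(calls)
  w <- params$window_snp
  if (n < w) return(logical(n))
  het <- !is.na(calls) & calls == 1L
  mis <- is.na(calls)
  win_het <- running_sum(as.integer(het), w)
  win_mis <- running_sum(as.integer(mis), w)
  hom_win <- win_het <= params$window_het_max & win_mis <= params$window_missing_max
  W <- n - w + 1L
  cs <- cumsum(c(0L, as.integer(hom_win)))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(W, i)
  n_win <- hi - lo + 1L
  n_hom <- cs[hi + 1L] - cs[lo]
  n_hom / n_win >= params$window_hit_threshold
}

call_roh_chrom <- function(calls, pos, params) {
  n <- length(calls)
  w <- params$window_snp
  empty <- data.frame(
    start = integer(0), end = integer(0),
    n_snps = integer(0), n_het = integer(0)
  )
  if (n < w) return(empty)
  het <- !is.na(calls) & calls == 1L
  flagged <- roh_flags(calls, params)

  r <- rle(flagged)
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    idx <- run_starts[k]:run_ends[k]
    # split at gaps larger than gap_max_kb before evaluating criteria
    gaps <- diff(pos[idx])
    cut_after <- which(gaps > params$gap_max_kb * 1000)
    piece_start <- c(1L, cut_after + 1L)
    piece_end <- c(cut_after, length(idx))
    for (p in seq_along(piece_start)) {
      pi <- idx[piece_start[p]:piece_end[p]]
      n_snps <- length(pi)
      len <- pos[pi[n_snps]] - pos[pi[1L]] + 1L
      n_het <- sum(het[pi])
      if (n_snps >= params$segment_snp_min &&
          len >= params$segment_kb_min * 1000 &&
          n_het <= params$segment_het_max &&
          (len / 1000) / n_snps <= params$density_min_kb_per_snp) {
        segs[[length(segs) + 1L]] <- data.frame(
          start = pos[pi[1L]], end = pos[pi[n_snps]],
          n_snps = n_snps, n_het = n_het
        )
      }
    }
  }
  if (!length(segs)) return(empty)
  do.call(rbind, segs)
}

#' Call runs of homozygosity
#'
#' Windowed ROH detection over all individuals and chromosomes of a genotype
#' matrix. Chromosomes with fewer SNPs than the window size yield no segments.
#'
#' @param gm a [genotype_matrix()].
#' @param params a [roh_params()].
#' @return data.frame of class `roh_segments` with columns individual, chrom,
#'   start, end, length_bp, n_snps, n_het.
#' @export
call_roh <- function(gm, params = roh_params()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(params, "roh_params"))
  res <- list()
  for (chr in unique(gm$sites$chrom)) {
    sel <- gm$sites$chrom == chr
    pos <- gm$sites$pos[sel]
    for (i in seq_len(n_ind(gm))) {
      segs <- call_roh_chrom(gm$calls[i, sel], pos, params)
      if (nrow(segs)) {
        segs$individual <- gm$individuals[i]
        segs$chrom <- chr
        res[[length(res) + 1L]] <- segs
      }
    }
  }
  if (!length(res)) {
    out <- data.frame(
      individual = character(0), chrom = character(0), start = integer(0),
      end = integer(0), length_bp = integer(0), n_snps = integer(0),
      n_het = integer(0), stringsAsFactors = FALSE
    )
  } else {
    out <- do.call(rbind, res)
    out$length_bp <- out$end - out$start + 1L
    out <- out[, c("individual", "chrom", "start", "end", "length_bp",
                   "n_snps", "n_het")]
    rownames(out) <- NULL
  }
  class(out) <- c("roh_segments", class(out))
  out
}

#' F_ROH inbreeding coefficient
#'
#' Total length of ROH longer than `froh_min_mb` megabases divided by the
#' autosomal genome length.
#'
#' @param segments `roh_segments` rows of one individual (or any subset).
#' @param autosome_length_bp total autosomal genome length in bp.
#' @param froh_min_mb tract-length threshold in Mb (strictly exceeded).
#' @return F_ROH in [0, 1].
#' @export
f_roh <- function(segments, autosome_length_bp, froh_min_mb = 10) {
  if (autosome_length_bp <= 0) stop("autosome_length_bp must be > 0")
  long <- segments$length_bp > froh_min_mb * 1e6
  sum(as.numeric(segments$length_bp[long])) / autosome_length_bp
}

#' Per-individual ROH profile
#'
#' Summaries per individual: segment count, total length, total length of
#' tracts above 5 Mb, and [f_roh()].
#'
#' @param segments a `roh_segments` data.frame (from [call_roh()]).
#' @param individuals individual IDs to report (so that individuals without
#'   any segment still appear); defaults to those present in `segments`.
#' @param autosome_length_bp total autosomal genome length in bp.
#' @param froh_min_mb threshold for F_ROH, in Mb.
#' @return data.frame with one row per individual.
#' @export
roh_profiles <- function(segments, autosome_length_bp,
                         individuals = unique(segments$individual),
                         froh_min_mb = 10) {
  rows <- lapply(individuals, function(id) {
    s <- segments[segments$individual == id, , drop = FALSE]
    data.frame(
      individual = id,
      n_segments = nrow(s),
      total_mb = sum(s$length_bp) / 1e6,
      total_gt5mb = sum(s$length_bp[s$length_bp > 5e6]) / 1e6,
      F_ROH = f_roh(s, autosome_length_bp, froh_min_mb),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' ROH tract-length distribution per population
#'
#' For every population and tract-length class, the proportion of sampled
#' individuals carrying at least one segment in that class. Default classes:
#' (1-5], (5-10], (10-20], (20-30] and > 30 Mb.
#'
#' @param segments a `roh_segments` data.frame.
#' @param popmap a [population_map()] covering the profiled individuals.
#' @param bin_edges_mb ascending bin edges in Mb (last class is open-ended).
#' @return data.frame with columns population, class, proportion.
#' @export
roh_length_distribution <- function(segments, popmap,
                                    bin_edges_mb = c(1, 5, 10, 20, 30)) {
  pops <- unique(popmap$assignments)
  edges <- c(bin_edges_mb, Inf)
  labels <- vapply(seq_len(length(edges) - 1L), function(i) {
    if (is.infinite(edges[i + 1L])) sprintf(">%g Mb", edges[i])
    else sprintf("(%g-%g] Mb", edges[i], edges[i + 1L])
  }, character(1))
  rows <- list()
  for (pop in pops) {
    inds <- population_individuals(popmap, pop)
    if (!length(inds)) stop("empty population: ", pop)
    for (b in seq_len(length(edges) - 1L)) {
      carrying <- vapply(inds, function(id) {
        len_mb <- segments$length_bp[segments$individual == id] / 1e6
        any(len_mb > edges[b] & len_mb <= edges[b + 1L])
      }, logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, class = labels[b],
        proportion = mean(carrying), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Write ROH segments as BED
#'
#' BED uses 0-based half-open coordinates; the inclusive 1-based segments are
#' converted at the boundary (`start - 1`, `end`).
#'
#' @param segments a `roh_segments` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roh_bed <- function(segments, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s",
    segments$chrom, segments$start - 1L, segments$end, segments$individual
  )
  writeLines(lines, path)
  invisible(path)
}
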