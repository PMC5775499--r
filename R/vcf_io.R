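#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file of biallelic SNPs (via Bioconductor's
#' \pkg{VariantAnnotation}) into a [genotype_matrix()]. Genotypes are collapsed
#' to unphased dosage; any genotype containing a missing allele (`./.` or
#' half-calls like `0/.`) becomes `NA`. If the file carries a per-genotype
#' `DP` field a [coverage_profile()] is returned alongside, using the `SF`
#' INFO field for per-site footprints when present, else `site_footprint`.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param site_footprint default per-site footprint in bp when the file does
#'   not record one.
#' @return list with elements `genotypes` (a `genotype_matrix`) and `coverage`
#'   (a `coverage_profile` or `NULL`).
#' @export
read_vcf <- function(path, site_footprint = 180L) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty VCF file: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) stop("failed to parse VCF ", path, ": ", conditionMessage(e))
  )
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  if (any(n_alt != 1L)) {
    i <- which(n_alt != 1L)[1L]
    stop(sprintf("multiallelic record at %s:%d", chrom[i], pos[i]))
  }
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(alt_list))
  if (any(nchar(ref) != 1L | nchar(alt) != 1L)) {
    i <- which(nchar(ref) != 1L | nchar(alt) != 1L)[1L]
    stop(sprintf("non-SNP record at %s:%d", chrom[i], pos[i]))
  }
  if (length(pos) > 1L) {
    for (chr in unique(chrom)) {
      p <- pos[chrom == chr]
      if (any(diff(p) <= 0L)) {
        stop("VCF positions not sorted/unique on ", chr)
      }
    }
    if (anyDuplicated(rle(chrom)$values)) {
      stop("VCF chromosome blocks are not contiguous (file unsorted)")
    }
  }
  gt <- VariantAnnotation::geno(vcf)$GT   # sites x samples
  if (is.null(gt)) stop("VCF has no GT field")
  calls <- t(gt_to_dosage(gt))            # individuals x sites
  sl <- GenomeInfoDb::seqlengths(rr)
  chrom_lengths <- if (all(is.na(sl))) NULL else sl[!is.na(sl)]
  gm <- genotype_matrix(
    calls = calls,
    sites = data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      stringsAsFactors = FALSE
    ),
    individuals = colnames(gt),
    chrom_lengths = chrom_lengths
  )
  cov <- NULL
  dp <- VariantAnnotation::geno(vcf)$DP
  if (!is.null(dp)) {
    fp <- VariantAnnotation::info(vcf)$SF
    fp <- if (is.null(fp) || all(is.na(fp))) site_footprint else as.integer(fp)
    cov <- coverage_profile(t(dp), site_footprint = fp)
  }
  list(genotypes = gm, coverage = cov)
}

gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  norm <- gsub("|", "/", u, fixed = TRUE)
  val <- vapply(strsplit(norm, "/", fixed = TRUE), function(a) {
    if (any(a == "." | a == "")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai) || any(ai > 1L)) {
      stop("unexpected allele code in genotype: ", paste(a, collapse = "/"))
    }
    sum(ai)
  }, integer(1))
  m <- matrix(val[match(as.vector(gt), u)], nrow = nrow(gt), ncol = ncol(gt))
  dimnames(m) <- dimnames(gt)
  m
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a sorted VCF 4.2 with GT (and DP when a coverage profile is supplied;
#' the per-site footprint goes into the `SF` INFO field so that coverage
#' round-trips). `read_vcf(write_vcf(gm))` is the identity.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param cov optional [coverage_profile()] aligned with `gm`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, cov = NULL) {
  validate_genotype_matrix(gm)
  if (!is.null(cov)) check_cov_aligned(gm, cov)
  con <- tryCatch(file(path, open = "wt"),
    error = function(e) stop("cannot write to ", path, ": ", conditionMessage(e))
  )
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=reintropop"
  )
  cl <- attr(gm, "chrom_lengths")
  chroms <- unique(gm$sites$chrom)
  if (is.null(cl)) {
    for (chr in chroms) hdr <- c(hdr, sprintf("##contig=<ID=%s>", chr))
  } else {
    for (chr in names(cl)) {
      hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", chr, as.integer(cl[[chr]])))
    }
  }
  if (!is.null(cov)) {
    hdr <- c(hdr, "##INFO=<ID=SF,Number=1,Type=Integer,Description=\"Site sequence footprint in bp\">")
  }
  hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(cov)) {
    hdr <- c(hdr, "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  }
  hdr <- c(hdr, paste(
    c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      gm$individuals),
    collapse = "\t"
  ))
  writeLines(hdr, con)
  if (n_sites(gm) > 0L) {
    gt_codes <- c("0/0", "0/1", "1/1")
    body <- vapply(seq_len(n_sites(gm)), function(j) {
      g <- gm$calls[, j]
      gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
      if (!is.null(cov)) {
        gt <- paste(gt, cov$depth[, j], sep = ":")
        info <- sprintf("SF=%d", cov$site_footprint[j])
        fmt <- "GT:DP"
      } else {
        info <- "."
        fmt <- "GT"
      }
      paste(c(
        gm$sites$chrom[j], gm$sites$pos[j], ".", gm$sites$ref[j],
        gm$sites$alt[j], ".", ".", info, fmt, gt
      ), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a population map file
#'
#' Whitespace- or tab-delimited text with three columns per line:
#' individual ID, population ID, demographic role. Lines starting with `#`
#' are ignored.
#'
#' @param path path to the map file.
#' @return a [population_map()].
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("population map is empty: ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    stop(sprintf(
      "malformed population map line %d (expected 3 fields, got %d)",
      lineno[which(nf != 3L)[1L]], nf[nf != 3L][1L]
    ))
  }
  tab <- do.call(rbind, parts)
  if (anyDuplicated(tab[, 1L])) {
    stop(
      "duplicate individual ID(s) in population map: ",
      paste(unique(tab[duplicated(tab[, 1L]), 1L]), collapse = ", ")
    )
  }
  assignments <- stats::setNames(tab[, 2L], tab[, 1L])
  roles_df <- unique(tab[, 2:3, drop = FALSE])
  if (anyDuplicated(roles_df[, 1L])) {
    stop("conflicting roles for population: ",
         roles_df[duplicated(roles_df[, 1L]), 1L][1L])
  }
  population_map(assignments, stats::setNames(roles_df[, 2L], roles_df[, 1L]))
}

#' Write a population map file
#' @param popmap a [population_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(popmap, path) {
  lines <- sprintf(
    "%s\t%s\t%s",
    names(popmap$assignments),
    popmap$assignments,
    popmap$roles[popmap$assignments]
  )
  writeLines(lines, path)
  invisible(path)
}
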