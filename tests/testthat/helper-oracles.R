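# Independent brute-force oracles. Deliberately written with naive loops and
# no shared code with the package internals.

# ROH oracle: literal three-stage scan.
oracle_roh <- function(calls, pos, params = roh_params()) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_snps = integer(0), n_het = integer(0))
  n <- length(calls)
  w <- params$window_snp
  if (n < w) return(empty)
  W <- n - w + 1L
  hom_win <- logical(W)
  for (s in seq_len(W)) {
    win <- calls[s:(s + w - 1L)]
    hom_win[s] <- sum(win == 1L, na.rm = TRUE) <= params$window_het_max &&
      sum(is.na(win)) <= params$window_missing_max
  }
  flag <- logical(n)
  for (i in seq_len(n)) {
    wins <- max(1L, i - w + 1L):min(W, i)
    flag[i] <- mean(hom_win[wins]) >= params$window_hit_threshold
  }
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (!flag[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && flag[j + 1L]) j <- j + 1L
    run <- i:j
    pieces <- list()
    cur <- run[1L]
    for (k in run[-1L]) {
      if (pos[k] - pos[cur[length(cur)]] > params$gap_max_kb * 1000) {
        pieces <- c(pieces, list(cur))
        cur <- integer(0)
      }
      cur <- c(cur, k)
    }
    pieces <- c(pieces, list(cur))
    for (pp in pieces) {
      ns <- length(pp)
      len <- pos[pp[ns]] - pos[pp[1L]] + 1L
      nh <- sum(calls[pp] == 1L, na.rm = TRUE)
      if (ns >= params$segment_snp_min &&
          len >= params$segment_kb_min * 1000 &&
          nh <= params$segment_het_max &&
          (len / 1000) / ns <= params$density_min_kb_per_snp) {
        segs[[length(segs) + 1L]] <- data.frame(
          start = pos[pp[1L]], end = pos[pp[ns]], n_snps = ns, n_het = nh
        )
      }
    }
    i <- j + 1L
  }
  if (!length(segs)) return(empty)
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# random genotype/position fixture for the ROH equivalence sweep
random_roh_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(30:250, 1L)
  # clustered positions so that oversized gaps occur
  gaps <- sample(c(2e4, 5e4, 2e5, 2e6), n, replace = TRUE,
                 prob = c(0.45, 0.4, 0.1, 0.05))
  pos <- cumsum(gaps)
  het_rate <- runif(1, 0.005, 0.3)
  mis_rate <- runif(1, 0, 0.25)
  u <- runif(n)
  calls <- ifelse(u < het_rate, 1L, ifelse(runif(n) < 0.5, 0L, 2L))
  calls[runif(n) < mis_rate] <- NA_integer_
  list(calls = as.integer(calls), pos = as.integer(pos))
}

# Weir & Cockerham (1984) two-population theta, scalar per-site loop.
oracle_wc_fst <- function(A, B) {
  num <- 0
  den <- 0
  for (j in seq_len(ncol(A))) {
    a_j <- A[, j][!is.na(A[, j])]
    b_j <- B[, j][!is.na(B[, j])]
    n1 <- length(a_j); n2 <- length(b_j)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(a_j) / (2 * n1); p2 <- sum(b_j) / (2 * n2)
    h1 <- mean(a_j == 1); h2 <- mean(b_j == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# interval overlap in bp between one interval and a set of intervals
overlap_bp <- function(start, end, starts, ends) {
  if (!length(starts)) return(0)
  sum(pmax(0, pmin(end, ends) - pmax(start, starts) + 1))
}
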