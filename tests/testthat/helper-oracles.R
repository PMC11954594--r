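# Independent oracles, written directly from first principles and kept free of
# the package's own code paths.

# Weir & Cockerham (1984) two-population diploid theta for ONE site, computed
# as a scalar transcription of the published component formulas.  Inputs are
# genotype vectors (0/1/2 = ALT allele count per individual, NA = missing).
oracle_wc_fst <- function(genoA, genoB) {
  r <- 2
  gA <- genoA[!is.na(genoA)]
  gB <- genoB[!is.na(genoB)]
  n1 <- length(gA); n2 <- length(gB)
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# EHH by definition: enumerate all pairs of core-allele carriers and count the
# pairs identical over every site between core and marker x (inclusive).
oracle_ehh_allpairs <- function(haps, core, allele, direction) {
  carriers <- which(haps[, core] == allele)
  n <- length(carriers)
  stopifnot(n >= 2)
  cols <- if (direction > 0) core:ncol(haps) else core:1
  denom <- choose(n, 2)
  vapply(seq_along(cols), function(k) {
    win <- cols[seq_len(k)]
    idents <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (all(haps[carriers[i], win] == haps[carriers[j], win]))
        idents <- idents + 1
    }
    idents / denom
  }, numeric(1))
}

# brute-force BED-convention overlap of 1-based hit positions with 0-based
# half-open elements
oracle_bed_overlap <- function(pos, start0, end0) {
  out <- matrix(FALSE, length(pos), length(start0))
  for (i in seq_along(pos)) for (j in seq_along(start0)) {
    out[i, j] <- start0[j] <= pos[i] - 1 && pos[i] - 1 < end0[j]
  }
  out
}

# exact two-sided rank-sum p-value by exhaustive enumeration of all
# choose(n1+n2, n1) assignments (small samples, no ties assumed)
oracle_ranksum_exact <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  combs <- utils::combn(N, n1)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n1 * (N + 1) / 2
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}

# add-one empirical p-value by direct counting
oracle_empirical_p <- function(null, obs) {
  vapply(obs, function(o) (1 + sum(null >= o)) / (length(null) + 1), numeric(1))
}
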