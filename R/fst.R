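#' Per-site Weir & Cockerham (1984) FST for a population pair
#'
#' Computes the diploid two-population variance components `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals, i.e. the observed-heterozygosity term) of Weir & Cockerham's
#' theta, and the per-site estimate `theta = a / (a + b + c)`.  Missing
#' genotypes are handled through the observed per-site sample sizes.  Sites
#' monomorphic across the pooled pair, or with fewer than two non-missing
#' genotypes in either population, are uninformative and get `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param manifest sample manifest (`sample_id`, `population`).
#' @param popA,popB population labels.
#' @return list with `fst` (per-site numeric), `informative` (logical) and
#'   `components` (data.frame: `a`, `b`, `c`, `n1`, `n2`, `p1`, `p2`,
#'   `h1`, `h2`).
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics for
#'   the analysis of population structure. Evolution 38:1358-1370.
#' @export
site_fst <- function(gm, manifest, popA, popB) {
  c1 <- pop_columns(gm, manifest, popA)
  c2 <- pop_columns(gm, manifest, popB)
  st1 <- pop_site_stats(gm, c1)
  st2 <- pop_site_stats(gm, c2)
  comp <- wc_components(st1$n, st1$p, st1$h, st2$n, st2$p, st2$h)
  denom <- comp$a + comp$b + comp$c
  pooled_alt <- st1$n * st1$p + st2$n * st2$p
  pooled_n <- st1$n + st2$n
  informative <- st1$n >= 2 & st2$n >= 2 &
    pooled_alt > 1e-12 & (pooled_n - pooled_alt) > 1e-12 &
    is.finite(denom) & denom > 0
  fst <- ifelse(informative, comp$a / denom, NA_real_)
  list(fst = fst, informative = informative,
       components = data.frame(a = comp$a, b = comp$b, c = comp$c,
                               n1 = st1$n, n2 = st2$n, p1 = st1$p, p2 = st2$p,
                               h1 = st1$h, h2 = st2$h))
}

## per-population per-site: non-missing diploid count, ALT freq, observed het
pop_site_stats <- function(gm, cols) {
  a1 <- gm$a1[, cols, drop = FALSE]
  a2 <- gm$a2[, cols, drop = FALSE]
  n <- rowSums(!is.na(a1))
  alt <- rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)
  het <- rowSums(a1 != a2, na.rm = TRUE)
  p <- ifelse(n > 0, alt / (2 * n), NA_real_)
  h <- ifelse(n > 0, het / n, NA_real_)
  list(n = n, p = p, h = h)
}

## vectorized W&C (1984) two-population diploid components (their eqs. 2-4
## specialised to r = 2 subpopulations)
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Weighted FST over sites
#'
#' Ratio-of-sums estimator: `sum(a) / sum(a + b + c)` over informative sites
#' (never the mean of per-site ratios).
#'
#' @param components component data.frame from [site_fst()].
#' @param informative logical vector marking informative sites (default: all
#'   rows with finite positive `a + b + c` denominators).
#' @return scalar weighted FST.
#' @export
weighted_fst <- function(components, informative = NULL) {
  denom <- components$a + components$b + components$c
  if (is.null(informative)) informative <- is.finite(denom) & denom > 0
  if (!any(informative)) stop("no informative sites for weighted FST")
  sum(components$a[informative]) / sum(denom[informative])
}

#' Pairwise weighted FST matrix over populations
#'
#' @param gm a [genotype_matrix()].
#' @param manifest sample manifest.
#' @return symmetric matrix of weighted FST with zero diagonal, labelled by
#'   population.  Pairs involving a population with fewer than two samples are
#'   `NA` with a warning.
#' @export
pairwise_fst_matrix <- function(gm, manifest) {
  pops <- unique(manifest$population)
  if (length(pops) < 2) stop("need at least two populations")
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  sizes <- table(manifest$population)[pops]
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (sizes[i] < 2 || sizes[j] < 2) {
      warning("population with < 2 samples: FST undefined for ",
              pops[i], " vs ", pops[j])
      m[i, j] <- m[j, i] <- NA_real_
      next
    }
    sf <- site_fst(gm, manifest, pops[i], pops[j])
    m[i, j] <- m[j, i] <- weighted_fst(sf$components, sf$informative)
  }
  m
}

#' Within- versus between-group comparison of pairwise FST
#'
#' Partitions the off-diagonal entries of a pairwise FST matrix into
#' within-region and between-region sets according to a population-to-region
#' grouping, and compares them with a two-sided Wilcoxon rank-sum test
#' (normal approximation with tie and continuity corrections, computed from
#' first principles).
#'
#' @param fst_matrix symmetric FST matrix from [pairwise_fst_matrix()].
#' @param grouping named character vector mapping each population (names) to a
#'   region.
#' @return list with `mean_within`, `mean_between`, `rank_sum_p`, and the two
#'   value sets.
#' @export
within_between_comparison <- function(fst_matrix, grouping) {
  pops <- rownames(fst_matrix)
  if (!all(pops %in% names(grouping)))
    stop("grouping must assign every population to a region")
  within <- c(); between <- c()
  for (i in seq_along(pops)[-1]) for (j in seq_len(i - 1)) {
    v <- fst_matrix[i, j]
    if (grouping[pops[i]] == grouping[pops[j]]) within <- c(within, v)
    else between <- c(between, v)
  }
  if (!length(within) || !length(between))
    stop("within/between partition is empty; check the grouping")
  list(mean_within = mean(within), mean_between = mean(between),
       rank_sum_p = rank_sum_p(within, between),
       within = within, between = between)
}

## two-sided Wilcoxon rank-sum p, normal approximation with tie correction
## and continuity correction
rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Population branch statistic
#'
#' Converts pairwise per-site FST into branch lengths `T = -ln(1 - FST)` and
#' returns the focal-population branch length
#' `PBS_A = (T_AB + T_AC - T_BC) / 2`.  FST values are clamped to
#' `[0, 1 - 1e-12]` before the log, so branch lengths are non-negative and
#' finite even at fixed differences; PBS is `NA` wherever any of the three
#' pairwise values is undefined.
#'
#' @param fst_ab,fst_ac,fst_bc per-site FST vectors for the focal/ingroup,
#'   focal/outgroup and ingroup/outgroup pairs (equal length).
#' @return per-site PBS vector for focal population A.
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc) {
  len <- c(length(fst_ab), length(fst_ac), length(fst_bc))
  if (length(unique(len[len > 1])) > 1)
    stop("FST vectors must have equal length")
  n <- max(len)
  fst_ab <- rep_len(fst_ab, n)
  fst_ac <- rep_len(fst_ac, n)
  fst_bc <- rep_len(fst_bc, n)
  (fst_branch(fst_ab) + fst_branch(fst_ac) - fst_branch(fst_bc)) / 2
}

#' FST to branch length
#' @param fst per-site FST vector (possibly negative or `NA`).
#' @return `-log(1 - fst)` after clamping `fst` into `[0, 1 - 1e-12]`.
#' @export
fst_branch <- function(fst) -log(1 - pmin(pmax(fst, 0), 1 - 1e-12))

#' Per-site FST and PBS table for a three-population trio
#'
#' Computes the three pairwise per-site FST vectors and the focal-population
#' PBS.  A pair that is monomorphic at a site which nevertheless segregates
#' across the trio (e.g. a variant private to the focal population, the
#' canonical PBS signal) contributes zero differentiation: its FST enters the
#' branch transform as 0 while the reported `fst_*` column keeps the `NA`
#' sentinel.  Sites monomorphic across all three populations, or with fewer
#' than two genotyped individuals in some population, have `NA` PBS.
#'
#' @param gm a [genotype_matrix()].
#' @param manifest sample manifest.
#' @param focal,ingroup,outgroup population labels (PBS is reported for
#'   `focal`).
#' @return data.frame with one row per site: variant key columns, the three
#'   pairwise FST values, branch lengths `t_ab`, `t_ac`, `t_bc` and `pbs`.
#' @export
pbs_table <- function(gm, manifest, focal, ingroup, outgroup) {
  st <- lapply(c(focal, ingroup, outgroup), function(p)
    pop_site_stats(gm, pop_columns(gm, manifest, p)))
  trio_alt <- st[[1]]$n * st[[1]]$p + st[[2]]$n * st[[2]]$p + st[[3]]$n * st[[3]]$p
  trio_n <- 2 * (st[[1]]$n + st[[2]]$n + st[[3]]$n)
  trio_poly <- trio_alt > 1e-9 & (trio_n - 2 * trio_alt) > 1e-9
  ok_n <- st[[1]]$n >= 2 & st[[2]]$n >= 2 & st[[3]]$n >= 2
  pair <- function(i, j) {
    comp <- wc_components(st[[i]]$n, st[[i]]$p, st[[i]]$h,
                          st[[j]]$n, st[[j]]$p, st[[j]]$h)
    denom <- comp$a + comp$b + comp$c
    alt <- st[[i]]$n * st[[i]]$p + st[[j]]$n * st[[j]]$p
    nn <- st[[i]]$n + st[[j]]$n
    mono <- alt <= 1e-9 | (2 * nn - 2 * alt) <= 1e-9
    fst <- ifelse(!mono & is.finite(denom) & denom > 0, comp$a / denom, NA_real_)
    list(fst = fst, mono = mono)
  }
  ab <- pair(1, 2); ac <- pair(1, 3); bc <- pair(2, 3)
  use <- function(p) ifelse(is.na(p$fst) & p$mono & trio_poly, 0, p$fst)
  u_ab <- use(ab); u_ac <- use(ac); u_bc <- use(bc)
  ok3 <- ok_n & !is.na(u_ab) & !is.na(u_ac) & !is.na(u_bc)
  t_ab <- ifelse(ok3, fst_branch(u_ab), NA_real_)
  t_ac <- ifelse(ok3, fst_branch(u_ac), NA_real_)
  t_bc <- ifelse(ok3, fst_branch(u_bc), NA_real_)
  data.frame(chrom = gm$chrom, pos = gm$pos, ref = gm$ref, alt = gm$alt,
             fst_ab = ab$fst, fst_ac = ac$fst, fst_bc = bc$fst,
             t_ab = t_ab, t_ac = t_ac, t_bc = t_bc,
             pbs = ifelse(ok3, (t_ab + t_ac - t_bc) / 2, NA_real_),
             stringsAsFactors = FALSE)
}
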