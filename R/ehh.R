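#' Phased haplotype matrix for one population
#'
#' Extracts the fully phased, fully observed biallelic-SNV haplotypes of one
#' population, oriented so 0 = ancestral and 1 = derived.  Sites that are
#' indels, unpolarized, unphased, or missing in any selected sample are
#' excluded (haplotype statistics require complete phased data); the retained
#' site count is reported in the `n_excluded` attribute.
#'
#' @param gm a polarized [genotype_matrix()].
#' @param manifest sample manifest.
#' @param population population label.
#' @return object of class `haplotype_matrix`: list with `haps` (2n haplotypes
#'   x m sites, 0/1), `chrom`, `pos`, and `hap_id`.
#' @export
haplotype_matrix <- function(gm, manifest, population) {
  cols <- pop_columns(gm, manifest, population)
  snv <- nchar(gm$ref) == 1 & nchar(gm$alt) == 1
  polar <- gm$anc_state != "unknown"
  complete <- rowSums(is.na(gm$a1[, cols, drop = FALSE])) == 0
  keep <- snv & polar & gm$phased & complete
  sub <- subset_gm(gm, sites = keep, samples = cols)
  m <- n_sites(sub)
  n <- length(cols)
  haps <- matrix(0L, 2 * n, m)
  haps[seq(1, 2 * n, by = 2), ] <- t(sub$a1)
  haps[seq(2, 2 * n, by = 2), ] <- t(sub$a2)
  flip <- sub$anc_state == "alt"     # orient: 1 = derived
  haps[, flip] <- 1L - haps[, flip]
  structure(list(haps = haps, chrom = sub$chrom, pos = sub$pos,
                 hap_id = paste0(rep(sub$samples, each = 2), c("_1", "_2"))),
            class = "haplotype_matrix",
            n_excluded = sum(!keep))
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix:", nrow(x$haps), "haplotypes x", ncol(x$haps), "sites\n")
  invisible(x)
}

#' Extended haplotype homozygosity decay from a core site
#'
#' EHH at marker x is the probability that two random haplotypes carrying
#' `core_allele` at the core are identical over every site between the core
#' and x inclusive: identical pairs / `choose(n_carriers, 2)`.  The curve
#' starts at the core (EHH = 1 by definition) and is computed outward until
#' the first value below `ehh_threshold` (reported, then stopped) or the
#' chromosome end.
#'
#' @param haps haplotype matrix (rows = haplotypes, 0/1 entries) or a
#'   [haplotype_matrix()] (single chromosome).
#' @param core_index column index of the core site.
#' @param core_allele 0 (ancestral) or 1 (derived).
#' @param direction `"left"` or `"right"`.
#' @param positions physical positions (bp) per column; defaults to those in a
#'   `haplotype_matrix`, else column index.
#' @param ehh_threshold stop threshold, default 0.05.
#' @return list with `pos` (starting at the core), `ehh` (starting at 1) and
#'   `hit_threshold` (did the curve fall below the threshold before the end?).
#' @export
ehh <- function(haps, core_index, core_allele, direction = c("right", "left"),
                positions = NULL, ehh_threshold = 0.05) {
  direction <- match.arg(direction)
  if (inherits(haps, "haplotype_matrix")) {
    if (length(unique(haps$chrom)) > 1)
      stop("EHH is defined within one chromosome")
    if (is.null(positions)) positions <- haps$pos
    haps <- haps$haps
  }
  if (is.null(positions)) positions <- seq_len(ncol(haps))
  carriers <- which(haps[, core_index] == core_allele)
  if (length(carriers) < 2)
    stop("fewer than 2 haplotypes carry the core allele; core skipped")
  side <- ehh_side_cpp(haps, carriers - 1L, core_index - 1L,
                       if (direction == "right") 1L else -1L, ehh_threshold)
  list(pos = c(positions[core_index], positions[side$cols + 1L]),
       ehh = c(1, side$ehh),
       hit_threshold = side$hit_threshold)
}

#' Integrated EHH over one decay curve
#'
#' Trapezoidal integral of an EHH curve over physical distance (bp), truncated
#' at the first point with EHH below `ehh_threshold` (that point excluded, no
#' interpolation) and at inter-marker gaps larger than `max_gap`.
#'
#' @param curve a curve from [ehh()] (list with `pos` and `ehh`, core first).
#' @param ehh_threshold integration cutoff, default 0.05.
#' @param max_gap largest allowed inter-marker gap in bp (default 200 kb);
#'   integration stops at the last marker before a larger gap.
#' @return scalar iHH (bp x EHH units) with logical attribute `truncated`:
#'   `TRUE` when integration ended at the curve end or a gap rather than by
#'   falling below the threshold.
#' @export
ihh <- function(curve, ehh_threshold = 0.05, max_gap = 2e5) {
  p <- curve$pos; e <- curve$ehh
  stopifnot(length(p) == length(e))
  if (length(e) == 0) return(structure(0, truncated = TRUE))
  last <- length(e)
  truncated <- TRUE
  for (i in seq_along(e)) {
    if (e[i] < ehh_threshold) { last <- i - 1L; truncated <- FALSE; break }
    if (i > 1 && abs(p[i] - p[i - 1]) > max_gap) { last <- i - 1L; break }
  }
  if (last < 2) return(structure(0, truncated = truncated))
  d <- abs(diff(p[seq_len(last)]))
  structure(sum(d * (e[seq_len(last - 1)] + e[2:last]) / 2),
            truncated = truncated)
}

## both-side iHH for one allele at one core
ihh_allele <- function(haps, positions, core_index, allele,
                       ehh_threshold, max_gap) {
  carriers <- which(haps[, core_index] == allele)
  if (length(carriers) < 2) return(list(ihh = NA_real_, truncated = FALSE))
  total <- 0; trunc <- FALSE
  for (dir in c(-1L, 1L)) {
    side <- ehh_side_cpp(haps, carriers - 1L, core_index - 1L, dir, ehh_threshold)
    v <- ihh(list(pos = c(positions[core_index], positions[side$cols + 1L]),
                  ehh = c(1, side$ehh)),
             ehh_threshold = ehh_threshold, max_gap = max_gap)
    # a side that ran to the chromosome end (or a gap) without dropping below
    # the threshold leaves the integral unbounded in principle
    trunc <- trunc || attr(v, "truncated")
    total <- total + as.numeric(v)
  }
  list(ihh = total, truncated = trunc)
}

#' Unstandardized iHS at one core site
#'
#' `iHS_raw = ln(iHH_ancestral / iHH_derived)`: negative values mean unusually
#' long derived haplotypes.  Cores where either allele's EHH never falls below
#' the threshold before the chromosome end (or a `max_gap` break) are flagged
#' `truncated`; cores with a zero iHH on either side are undefined (`NA`).
#'
#' @param haps 0/1 haplotype matrix (1 = derived) or [haplotype_matrix()].
#' @param core_index column index of the core site.
#' @param positions physical positions per column.
#' @inheritParams ihh
#' @return list with `ihh_a`, `ihh_d`, `ihs_raw`, `truncated`, `daf`.
#' @export
ihs_raw <- function(haps, core_index, positions = NULL,
                    ehh_threshold = 0.05, max_gap = 2e5) {
  if (inherits(haps, "haplotype_matrix")) {
    if (is.null(positions)) positions <- haps$pos
    haps <- haps$haps
  }
  if (is.null(positions)) positions <- seq_len(ncol(haps))
  a <- ihh_allele(haps, positions, core_index, 0L, ehh_threshold, max_gap)
  d <- ihh_allele(haps, positions, core_index, 1L, ehh_threshold, max_gap)
  raw <- if (is.na(a$ihh) || is.na(d$ihh) || a$ihh == 0 || d$ihh == 0)
    NA_real_ else log(a$ihh / d$ihh)
  list(ihh_a = a$ihh, ihh_d = d$ihh, ihs_raw = raw,
       truncated = a$truncated || d$truncated,
       daf = mean(haps[, core_index]))
}

#' Genome-wide raw iHS scan
#'
#' Computes [ihs_raw()] at every core site whose derived allele frequency lies
#' in `[maf, 1 - maf]`, chromosome by chromosome.
#'
#' @param hm a [haplotype_matrix()].
#' @param maf minor (derived) frequency bound for usable cores, default 0.05.
#' @inheritParams ihh
#' @return data.frame: `chrom`, `pos`, `daf`, `ihh_a`, `ihh_d`, `ihs_raw`,
#'   `truncated` (one row per evaluated core).
#' @export
ihs_scan <- function(hm, maf = 0.05, ehh_threshold = 0.05, max_gap = 2e5) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  out <- list()
  for (ch in unique(hm$chrom)) {
    j <- which(hm$chrom == ch)
    haps <- hm$haps[, j, drop = FALSE]
    pos <- hm$pos[j]
    daf <- colMeans(haps)
    cores <- which(daf >= maf & daf <= 1 - maf &
                     colSums(haps) >= 2 & colSums(1L - haps) >= 2)
    if (!length(cores)) next
    vals <- vapply(cores, function(k) {
      r <- ihs_raw(haps, k, positions = pos,
                   ehh_threshold = ehh_threshold, max_gap = max_gap)
      c(r$daf, r$ihh_a, r$ihh_d, r$ihs_raw, as.numeric(r$truncated))
    }, numeric(5))
    out[[ch]] <- data.frame(chrom = ch, pos = pos[cores], daf = vals[1, ],
                            ihh_a = vals[2, ], ihh_d = vals[3, ],
                            ihs_raw = vals[4, ], truncated = vals[5, ] > 0,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(), daf = numeric(),
                      ihh_a = numeric(), ihh_d = numeric(), ihs_raw = numeric(),
                      truncated = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Standardize iHS within derived-frequency bins
#'
#' Bins cores by derived allele frequency, centres and scales `ihs_raw` within
#' each bin (sample standard deviation, denominator n - 1), and converts to
#' two-sided Gaussian p-values `p = 2 * pnorm(-|iHS_std|)`.  Truncated cores
#' and cores in bins with fewer than `min_bin_count` usable members (or zero
#' spread) are flagged and left unstandardized.
#'
#' @param table data.frame from [ihs_scan()].
#' @param bin_width derived-frequency bin width, default 0.025.
#' @param min_bin_count smallest usable bin size, default 10.
#' @return the table with added columns `bin`, `ihs_std`, `pvalue`, `flag`
#'   (`"ok"`, `"truncated"`, `"undefined"` or `"unstandardized"`).
#' @export
standardize_ihs <- function(table, bin_width = 0.025, min_bin_count = 10) {
  bin <- pmin(floor(table$daf / bin_width), ceiling(1 / bin_width) - 1)
  usable <- !table$truncated & !is.na(table$ihs_raw)
  flag <- ifelse(table$truncated, "truncated",
                 ifelse(is.na(table$ihs_raw), "undefined", "ok"))
  ihs_std <- rep(NA_real_, nrow(table))
  for (b in unique(bin[usable])) {
    i <- which(bin == b & usable)
    if (length(i) < min_bin_count) { flag[i] <- "unstandardized"; next }
    s <- stats::sd(table$ihs_raw[i])
    if (!is.finite(s) || s == 0) { flag[i] <- "unstandardized"; next }
    ihs_std[i] <- (table$ihs_raw[i] - mean(table$ihs_raw[i])) / s
  }
  table$bin <- bin
  table$ihs_std <- ihs_std
  table$pvalue <- 2 * stats::pnorm(-abs(ihs_std))
  table$flag <- flag
  table
}
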