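#' Diploid genotype matrix
#'
#' The central container all scan stages consume: biallelic variants in rows,
#' samples in columns, with each diploid genotype stored as a pair of allele
#' indices (0 = REF, 1 = ALT, `NA` = missing).  Variants carry a per-record
#' phase flag and an ancestral-state code (`"ref"`, `"alt"` or `"unknown"`)
#' filled in by [polarize()].
#'
#' @param chrom character vector of chromosome labels, one per variant.
#' @param pos integer vector of 1-based physical positions (bp); must be
#'   strictly increasing within each chromosome.
#' @param ref,alt allele strings; `ref != alt` at every record.
#' @param a1,a2 integer matrices (variants x samples) holding the first and
#'   second allele index of each genotype; entries 0, 1 or `NA`.
#' @param phased logical vector, one per variant: were the GT calls phased?
#' @param samples character vector of sample identifiers (column names).
#' @param anc_state character vector in `c("ref", "alt", "unknown")`.
#'
#' @return An object of class `genotype_matrix`.
#' @seealso [read_vcf()], [filter_sites()], [polarize()]
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, a1, a2, phased, samples,
                            anc_state = rep("unknown", length(pos))) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            length(phased) == n, length(anc_state) == n,
            is.matrix(a1), is.matrix(a2),
            nrow(a1) == n, nrow(a2) == n,
            ncol(a1) == length(samples), ncol(a2) == length(samples))
  if (any(ref == alt))
    stop("REF equals ALT at record(s): ",
         paste(which(ref == alt)[seq_len(min(5, sum(ref == alt)))], collapse = ", "))
  bad <- !(a1 %in% c(0L, 1L, NA)) | !(a2 %in% c(0L, 1L, NA))
  if (any(bad))
    stop("genotype entries must be 0, 1 or NA")
  if (any(is.na(a1) != is.na(a2)))
    stop("half-missing genotypes are not representable; both alleles must be missing")
  if (!all(anc_state %in% c("ref", "alt", "unknown")))
    stop("anc_state must be 'ref', 'alt' or 'unknown'")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  dimnames(a1) <- dimnames(a2) <- NULL
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         a1 = a1, a2 = a2, phased = as.logical(phased),
         anc_state = anc_state, samples = as.character(samples)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_sites(x), "variants x", length(x$samples), "samples\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  cat("  phased records:", sum(x$phased), "/", n_sites(x), "\n")
  cat("  ancestral state: ref =", sum(x$anc_state == "ref"),
      " alt =", sum(x$anc_state == "alt"),
      " unknown =", sum(x$anc_state == "unknown"), "\n")
  invisible(x)
}

#' Number of variant records
#' @param gm a [genotype_matrix()].
#' @return integer count of variant rows.
#' @export
n_sites <- function(gm) length(gm$pos)

#' Subset a genotype matrix by site and/or sample
#'
#' @param gm a [genotype_matrix()].
#' @param sites logical or integer index over variant rows.
#' @param samples logical, integer or character index over samples.
#' @return a `genotype_matrix` restricted to the selection.
#' @export
subset_gm <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(gm))
  scol <- seq_along(gm$samples)
  if (!is.null(samples)) {
    scol <- if (is.character(samples)) match(samples, gm$samples) else scol[samples]
    if (anyNA(scol)) stop("unknown sample(s) requested")
  }
  genotype_matrix(gm$chrom[sites], gm$pos[sites], gm$ref[sites], gm$alt[sites],
                  gm$a1[sites, scol, drop = FALSE], gm$a2[sites, scol, drop = FALSE],
                  gm$phased[sites], gm$samples[scol], gm$anc_state[sites])
}

#' Variant keys
#'
#' @param gm a [genotype_matrix()].
#' @return character vector `chrom:pos:ref:alt`, the canonical variant key
#'   used for merging and cross-referencing.
#' @export
variant_key <- function(gm) paste(gm$chrom, gm$pos, gm$ref, gm$alt, sep = ":")

## column indices of a population's samples, with validation
pop_columns <- function(gm, manifest, population) {
  if (!population %in% manifest$population)
    stop("population '", population, "' not present in manifest")
  ids <- manifest$sample_id[manifest$population == population]
  cols <- match(ids, gm$samples)
  if (anyNA(cols))
    stop("manifest sample(s) missing from genotype matrix: ",
         paste(ids[is.na(cols)], collapse = ", "))
  cols
}

## per-site ALT allele count and non-missing allele count over given columns
alt_allele_counts <- function(gm, cols) {
  a1 <- gm$a1[, cols, drop = FALSE]
  a2 <- gm$a2[, cols, drop = FALSE]
  list(alt = rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE),
       n = rowSums(!is.na(a1)) + rowSums(!is.na(a2)))
}

#' Derived allele frequency per site within one population
#'
#' Uses the ancestral-state annotation set by [polarize()]: the derived allele
#' is ALT where REF is ancestral and REF where ALT is ancestral.  Sites with
#' unknown ancestral state, and sites at which the population has no
#' non-missing alleles, return `NA`.
#'
#' @param gm a polarized [genotype_matrix()].
#' @param manifest sample manifest (`sample_id`, `population`).
#' @param population population label to evaluate.
#' @return numeric vector of derived allele frequencies (one per site).
#' @export
derived_allele_freq <- function(gm, manifest, population) {
  cols <- pop_columns(gm, manifest, population)
  ac <- alt_allele_counts(gm, cols)
  freq_alt <- ifelse(ac$n > 0, ac$alt / ac$n, NA_real_)
  out <- ifelse(gm$anc_state == "ref", freq_alt,
                ifelse(gm$anc_state == "alt", 1 - freq_alt, NA_real_))
  out[ac$n == 0] <- NA_real_
  out
}

#' Read a sample-to-population manifest
#'
#' @param path TSV with header columns `sample_id` and `population`.
#' @return data.frame with unique sample ids.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(m)))
    stop("manifest must have columns sample_id, population")
  validate_manifest(m)
  m[c("sample_id", "population")]
}

#' Write a sample manifest
#' @param manifest data.frame (`sample_id`, `population`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  if (anyDuplicated(m$sample_id))
    stop("duplicated sample id(s) in manifest: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  if (any(!nzchar(m$population)) || anyNA(m$population))
    stop("every sample needs a non-empty population label")
  invisible(m)
}
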