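#' Merge variant cohorts on shared sites
#'
#' Inner join of two or more genotype matrices on the `(chrom, pos, ref, alt)`
#' key: sites absent from any cohort are dropped, sample columns are the
#' concatenation of the manifests in order.  Sites where two cohorts carry the
#' same position with REF and ALT exchanged are an error (no automatic allele
#' flipping); an identical reference build is assumed.
#'
#' @param matrices list of [genotype_matrix()] objects.
#' @param manifests list of manifests (same length/order), each a data.frame
#'   with `sample_id` and `population`; sample ids must be globally unique.
#' @return `list(gm = merged genotype_matrix, manifest = combined manifest)`.
#' @export
merge_cohorts <- function(matrices, manifests) {
  stopifnot(length(matrices) >= 2, length(matrices) == length(manifests))
  manifest <- do.call(rbind, manifests)
  validate_manifest(manifest)
  keys <- lapply(matrices, variant_key)
  poskeys <- lapply(matrices, function(g) paste(g$chrom, g$pos, sep = ":"))
  swapkeys <- lapply(matrices, function(g) paste(g$chrom, g$pos, g$alt, g$ref, sep = ":"))
  for (j in 2:length(matrices)) {
    swapped <- intersect(keys[[1]], swapkeys[[j]])
    # a true key match at the same position is not a swap
    swapped <- setdiff(swapped, keys[[j]])
    if (length(swapped))
      stop("REF/ALT swapped between cohorts at: ", paste(swapped, collapse = ", "))
  }
  shared <- Reduce(intersect, keys)
  if (!length(shared)) {
    warning("cohorts share no variant sites; merged matrix is empty")
  }
  idx1 <- which(keys[[1]] %in% shared)           # preserve first cohort's order
  shared <- keys[[1]][idx1]
  g1 <- matrices[[1]]
  a1 <- g1$a1[idx1, , drop = FALSE]
  a2 <- g1$a2[idx1, , drop = FALSE]
  phased <- g1$phased[idx1]
  anc <- g1$anc_state[idx1]
  for (j in 2:length(matrices)) {
    gj <- matrices[[j]]
    ij <- match(shared, keys[[j]])
    a1 <- cbind(a1, gj$a1[ij, , drop = FALSE])
    a2 <- cbind(a2, gj$a2[ij, , drop = FALSE])
    phased <- phased & gj$phased[ij]
    anc2 <- gj$anc_state[ij]
    conflict <- anc != "unknown" & anc2 != "unknown" & anc != anc2
    if (any(conflict))
      stop("conflicting ancestral annotations at: ",
           paste(shared[conflict], collapse = ", "))
    anc[anc == "unknown"] <- anc2[anc == "unknown"]
  }
  gm <- genotype_matrix(g1$chrom[idx1], g1$pos[idx1], g1$ref[idx1], g1$alt[idx1],
                        a1, a2, phased, manifest$sample_id, anc)
  list(gm = gm, manifest = manifest)
}

#' Site-level quality filters
#'
#' Keeps sites whose missing-genotype fraction is at most `max_missing_frac`
#' AND whose pooled minor allele frequency is strictly greater than `min_maf`
#' AND (when `autosomes_only`) whose chromosome is in the autosome set.  MAF
#' is computed over all retained samples pooled, from observed (non-missing)
#' alleles.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing_frac maximum tolerated fraction of missing genotypes per
#'   site, in `[0, 1]`; default 0.008.
#' @param min_maf pooled minor-allele-frequency threshold (strict), default 0.05.
#' @param autosomes_only drop sites outside `autosomes`?
#' @param autosomes chromosome labels counted as autosomal.
#' @return `list(gm = filtered genotype_matrix, report = data.frame)` where the
#'   report gives site counts per filter stage (removed + retained = input).
#' @export
filter_sites <- function(gm, max_missing_frac = 0.008, min_maf = 0.05,
                         autosomes_only = FALSE,
                         autosomes = c(as.character(1:22), paste0("chr", 1:22))) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1,
            min_maf >= 0, min_maf <= 1)
  n_in <- n_sites(gm)
  keep <- rep(TRUE, n_in)
  rm_auto <- 0L
  if (autosomes_only) {
    fail <- !(gm$chrom %in% autosomes)
    rm_auto <- sum(keep & fail)
    keep <- keep & !fail
  }
  miss_frac <- rowMeans(is.na(gm$a1))
  fail_miss <- miss_frac > max_missing_frac
  rm_miss <- sum(keep & fail_miss)
  keep <- keep & !fail_miss
  ac <- alt_allele_counts(gm, seq_along(gm$samples))
  f <- ifelse(ac$n > 0, ac$alt / ac$n, 0)
  maf <- pmin(f, 1 - f)
  fail_maf <- !(maf > min_maf)
  rm_maf <- sum(keep & fail_maf)
  keep <- keep & !fail_maf
  if (!any(keep)) warning("no sites retained after filtering")
  report <- data.frame(
    stage = c("input", "autosome", "missingness", "maf", "retained"),
    removed = c(0L, rm_auto, rm_miss, rm_maf, 0L),
    remaining = c(n_in, n_in - rm_auto, n_in - rm_auto - rm_miss,
                  n_in - rm_auto - rm_miss - rm_maf, sum(keep)))
  list(gm = subset_gm(gm, sites = keep), report = report)
}

#' Polarize variants against an ancestral-allele table
#'
#' Sets the per-site ancestral state by matching the ancestral base
#' (case-insensitively) to REF or ALT.  Sites with no table entry, or whose
#' ancestral base matches neither allele, are unpolarizable: retained with
#' state `"unknown"` under `mode = "keep_all"`, removed under
#' `mode = "drop_unpolarized"`.
#'
#' @param gm a [genotype_matrix()].
#' @param ancestral data.frame from [read_ancestral()] (`chrom`, `pos`,
#'   `ancestral`).
#' @param mode `"keep_all"` (default) or `"drop_unpolarized"`.
#' @return a `genotype_matrix` with `anc_state` filled in.
#' @export
polarize <- function(gm, ancestral, mode = c("keep_all", "drop_unpolarized")) {
  mode <- match.arg(mode)
  i <- match(paste(gm$chrom, gm$pos, sep = ":"),
             paste(ancestral$chrom, ancestral$pos, sep = ":"))
  base <- toupper(ancestral$ancestral[i])
  is_ref <- !is.na(base) & toupper(gm$ref) == base
  is_alt <- !is.na(base) & toupper(gm$alt) == base
  stopifnot(!any(is_ref & is_alt))   # impossible while ref != alt
  state <- ifelse(is_ref, "ref", ifelse(is_alt, "alt", "unknown"))
  out <- gm
  out$anc_state <- state
  if (mode == "drop_unpolarized")
    out <- subset_gm(out, sites = state != "unknown")
  out
}
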