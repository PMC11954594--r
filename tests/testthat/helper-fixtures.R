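# programmatic fixtures; nothing is stored on disk

# genotype matrix from per-population genotype-count matrices
# geno: list of integer vectors (0/1/2/NA per individual) per site per pop
gm_from_genotypes <- function(genoA, genoB, chrom = "1") {
  # genoA/genoB: sites x individuals matrices of ALT counts
  stopifnot(nrow(genoA) == nrow(genoB))
  n <- nrow(genoA)
  split_geno <- function(g) {
    a1 <- ifelse(is.na(g), NA_integer_, as.integer(g >= 1))
    a2 <- ifelse(is.na(g), NA_integer_, as.integer(g == 2))
    list(a1 = a1, a2 = a2)
  }
  gA <- split_geno(genoA); gB <- split_geno(genoB)
  samples <- c(paste0("A", seq_len(ncol(genoA))), paste0("B", seq_len(ncol(genoB))))
  gm <- genotype_matrix(rep(chrom, n), seq_len(n) * 100L,
                        rep("A", n), rep("G", n),
                        cbind(gA$a1, gB$a1), cbind(gA$a2, gB$a2),
                        rep(TRUE, n), samples)
  manifest <- data.frame(sample_id = samples,
                         population = rep(c("A", "B"),
                                          c(ncol(genoA), ncol(genoB))))
  list(gm = gm, manifest = manifest)
}

# random small two-population genotype configuration
random_geno_pair <- function(n_sites = 1, nA = 6, nB = 8) {
  p <- runif(1, 0.1, 0.9)
  q <- runif(1, 0.1, 0.9)
  genoA <- matrix(rbinom(n_sites * nA, 2, p), n_sites)
  genoB <- matrix(rbinom(n_sites * nB, 2, q), n_sites)
  list(genoA = genoA, genoB = genoB)
}

# tiny handwritten VCF on disk
write_toy_vcf <- function(path, gts = c("0|1", "1|1", "./."),
                          samples = c("s1", "s2", "s3"),
                          pos = c(100L, 200L, 300L)) {
  n <- length(pos)
  gt <- matrix(gts, n, length(samples))
  body <- vapply(seq_len(n), function(i)
    paste(c("1", pos[i], ".", "A", "G", ".", "PASS", ".", "GT", gt[i, ]),
          collapse = "\t"), "")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body), path)
  path
}

# hand-drawn toy gene model: one plus-strand coding gene spanning 1000-2000
# with exons [1000,1200] and [1800,2000] and CDS [1050,1150] + [1800,1900]
toy_gene_model <- function(strand = "+") {
  data.frame(gene = "TOY1", chrom = "1", strand = strand,
             tx_start = 1000L, tx_end = 2000L,
             exon_starts = "1000,1800", exon_ends = "1200,2000",
             cds_starts = "1050,1800", cds_ends = "1150,1900",
             stringsAsFactors = FALSE)
}

# small three-population dataset reused by several scan tests (cached)
cached_small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_three_pop_dataset(
        sweep = NULL, seed = 42L, n_background = 600,
        background_chroms = as.character(1:3),
        sample_config = c(outgroup = 30, ingroup = 30, focal = 40))
    }
    cache
  }
})
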