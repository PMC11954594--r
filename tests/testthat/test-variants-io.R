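test_that("VCF reading parses genotypes, phase and missingness", {
  f <- write_toy_vcf(tempfile(fileext = ".vcf"),
                     gts = c("0|1", "1/1", "./."))
  gm <- read_vcf(f)
  expect_equal(n_sites(gm), 3)
  expect_equal(length(gm$samples), 3)
  expect_equal(gm$a1[1, 1], 0L)
  expect_equal(gm$a2[1, 1], 1L)
  expect_true(gm$phased[1])        # all calls on record 1 use |
  expect_false(gm$phased[2])       # record 2 uses /
  expect_true(all(is.na(gm$a1[3, ])))
})

test_that("VCF writing round-trips chrom/pos/ref/alt/GT", {
  set.seed(11)
  g <- random_geno_pair(8, 5, 5)
  fx <- gm_from_genotypes(g$genoA, g$genoB)
  f <- tempfile(fileext = ".vcf")
  write_vcf(fx$gm, f)
  back <- read_vcf(f)
  expect_identical(back$chrom, fx$gm$chrom)
  expect_identical(back$pos, fx$gm$pos)
  expect_identical(back$ref, fx$gm$ref)
  expect_identical(back$alt, fx$gm$alt)
  expect_identical(back$a1, fx$gm$a1)
  expect_identical(back$a2, fx$gm$a2)
  expect_identical(back$phased, fx$gm$phased)
})

test_that("malformed VCF records are hard errors naming the problem", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t"),
               "1\t100\t.\tA\tG,T\t.\t.\t.\tGT\t0/1"), f)
  expect_error(read_vcf(f), "multiallelic")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t"),
               "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1",
               "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0"), f)
  expect_error(read_vcf(f), "duplicated")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t"),
               "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1/1"), f)
  expect_error(read_vcf(f), "non-diploid|malformed")
})

test_that("merge_cohorts is an inner join with swap detection", {
  mk <- function(pos, ref = "A", alt = "G", prefix = "x") {
    n <- length(pos)
    genotype_matrix(rep("1", n), pos, rep(ref, n), rep(alt, n),
                    matrix(0L, n, 2), matrix(1L, n, 2), rep(TRUE, n),
                    paste0(prefix, 1:2))
  }
  man <- function(prefix, pop) data.frame(sample_id = paste0(prefix, 1:2),
                                          population = pop)
  m <- merge_cohorts(list(mk(c(100L, 200L, 300L), prefix = "a"),
                          mk(c(100L, 300L), prefix = "b")),
                     list(man("a", "A"), man("b", "B")))
  expect_equal(m$gm$pos, c(100L, 300L))          # set intersection by hand
  expect_equal(length(m$gm$samples), 4)

  same <- merge_cohorts(list(mk(c(100L, 200L), prefix = "a"),
                             mk(c(100L, 200L), prefix = "b")),
                        list(man("a", "A"), man("b", "B")))
  expect_equal(n_sites(same$gm), 2)              # idempotent on shared sites

  expect_warning(
    empty <- merge_cohorts(list(mk(100L, prefix = "a"), mk(200L, prefix = "b")),
                           list(man("a", "A"), man("b", "B"))),
    "no variant sites")
  expect_equal(n_sites(empty$gm), 0)

  swapped <- genotype_matrix("1", 100L, "G", "A", matrix(0L, 1, 2),
                             matrix(1L, 1, 2), TRUE, paste0("c", 1:2))
  expect_error(merge_cohorts(list(mk(100L, prefix = "a"), swapped),
                             list(man("a", "A"), man("c", "C"))),
               "swapped")
})

test_that("filter_sites applies missingness, MAF and autosome rules", {
  # 159 samples; site 1: 1 missing genotype (1/159 <= 0.008, kept);
  # site 2: 2 missing (removed); site 3: MAF exactly 0.05 (removed, strict >)
  n_s <- 159
  a1 <- matrix(0L, 3, n_s); a2 <- matrix(0L, 3, n_s)
  a1[1:2, 1:60] <- 1L; a2[1:2, 1:60] <- 1L       # common variant
  a1[1, 1] <- a2[1, 1] <- NA
  a1[2, 1:2] <- a2[2, 1:2] <- NA
  a1[3, seq_len(15)] <- 1L                       # 15/318 alt alleles ≈ 0.047
  gm <- genotype_matrix(rep("1", 3), c(1L, 2L, 3L), rep("A", 3), rep("G", 3),
                        a1, a2, rep(TRUE, 3), paste0("s", 1:n_s))
  expect_equal(mean(is.na(gm$a1[1, ])), 1 / 159)
  res <- filter_sites(gm, max_missing_frac = 0.008, min_maf = 0.05)
  expect_equal(n_sites(res$gm), 1)
  expect_equal(res$gm$pos, 1L)
  # report is conserved and re-filtering is a no-op
  rep_tab <- res$report
  expect_equal(rep_tab$remaining[rep_tab$stage == "retained"],
               rep_tab$remaining[1] - sum(rep_tab$removed))
  again <- filter_sites(res$gm, 0.008, 0.05)
  expect_equal(n_sites(again$gm), n_sites(res$gm))

  # MAF exactly at the threshold is removed (strict inequality)
  maf04 <- genotype_matrix("1", 1L, "A", "G",
                           matrix(c(rep(1L, 4), rep(0L, 46)), 1),
                           matrix(0L, 1, 50), TRUE, paste0("s", 1:50))
  suppressWarnings(
    expect_equal(n_sites(filter_sites(maf04, min_maf = 0.05)$gm), 0))

  # monomorphic input retains nothing
  mono <- genotype_matrix("1", 1L, "A", "G", matrix(0L, 1, 10),
                          matrix(0L, 1, 10), TRUE, paste0("s", 1:10))
  expect_warning(res0 <- filter_sites(mono), "no sites")
  expect_equal(n_sites(res0$gm), 0)

  # autosome filter
  gmx <- genotype_matrix(c("1", "X"), c(1L, 1L), c("A", "A"), c("G", "G"),
                         matrix(c(0L, 0L, 1L, 1L), 2), matrix(1L, 2, 2),
                         c(TRUE, TRUE), c("s1", "s2"))
  resx <- filter_sites(gmx, max_missing_frac = 1, min_maf = 0,
                       autosomes_only = TRUE)
  expect_equal(resx$gm$chrom, "1")
})

test_that("polarize assigns ancestral states and can drop unpolarized sites", {
  gm <- genotype_matrix(rep("1", 3), c(10L, 20L, 30L),
                        c("A", "A", "A"), c("G", "G", "G"),
                        matrix(0L, 3, 2), matrix(1L, 3, 2),
                        rep(TRUE, 3), c("s1", "s2"))
  anc <- data.frame(chrom = "1", pos = c(10L, 20L, 30L),
                    ancestral = c("a", "G", "C"))
  p <- polarize(gm, anc)
  expect_equal(p$anc_state, c("ref", "alt", "unknown"))  # case-insensitive
  d <- polarize(gm, anc, mode = "drop_unpolarized")
  expect_equal(n_sites(d), 2)

  # 10 sites, 3 unpolarizable, keep_all retains all with unknown flags
  gm10 <- genotype_matrix(rep("1", 10), 1:10 * 10L, rep("A", 10), rep("G", 10),
                          matrix(0L, 10, 2), matrix(1L, 10, 2),
                          rep(TRUE, 10), c("s1", "s2"))
  anc10 <- data.frame(chrom = "1", pos = 1:10 * 10L,
                      ancestral = c(rep("A", 4), rep("G", 3), rep("T", 3)))
  p10 <- polarize(gm10, anc10, mode = "keep_all")
  expect_equal(n_sites(p10), 10)
  expect_equal(sum(p10$anc_state == "unknown"), 3)
})

test_that("derived allele frequencies match brute-force allele counting", {
  # 4 diploids, derived allele count 2 of 8
  gm <- genotype_matrix("1", 1L, "A", "G",
                        matrix(c(1L, 1L, 0L, 0L), 1),
                        matrix(0L, 1, 4), TRUE, paste0("s", 1:4),
                        anc_state = "ref")
  man <- data.frame(sample_id = paste0("s", 1:4), population = "p")
  expect_equal(derived_allele_freq(gm, man, "p"), 0.25)

  # all samples missing -> undefined
  gmm <- genotype_matrix("1", 1L, "A", "G", matrix(NA_integer_, 1, 4),
                         matrix(NA_integer_, 1, 4), TRUE, paste0("s", 1:4),
                         anc_state = "ref")
  expect_true(is.na(derived_allele_freq(gmm, man, "p")))

  # mixed toy vs enumeration, including ALT-ancestral orientation
  set.seed(3)
  a1 <- matrix(rbinom(20, 1, 0.4), 5); a2 <- matrix(rbinom(20, 1, 0.4), 5)
  anc_state <- c("ref", "alt", "ref", "alt", "unknown")
  gm5 <- genotype_matrix(rep("1", 5), 1:5 * 10L, rep("A", 5), rep("G", 5),
                         a1, a2, rep(TRUE, 5), paste0("s", 1:4), anc_state)
  got <- derived_allele_freq(gm5, man, "p")
  for (i in 1:5) {
    alleles <- c(a1[i, ], a2[i, ])
    expected <- switch(anc_state[i],
                       ref = mean(alleles), alt = 1 - mean(alleles),
                       unknown = NA_real_)
    expect_equal(got[i], expected)
  }
})

test_that("manifest and ancestral-table IO validate their contracts", {
  f <- tempfile(fileext = ".tsv")
  write_manifest(data.frame(sample_id = c("a", "b"),
                            population = c("p", "q")), f)
  m <- read_manifest(f)
  expect_equal(m$population, c("p", "q"))
  writeLines("sample_id\tpopulation\na\tp\na\tq", f)
  expect_error(read_manifest(f), "duplicated")

  write_ancestral(data.frame(chrom = "1", pos = 5L, ancestral = "A"), f)
  expect_equal(read_ancestral(f)$ancestral, "A")
  writeLines("chrom\tpos\tancestral\n1\t5\tN", f)
  expect_error(read_ancestral(f), "A, C, G or T")
})
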