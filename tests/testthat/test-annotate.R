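test_that("genic classification walks the hand-drawn toy model correctly", {
  g <- toy_gene_model("+")   # gene 1000-2000, exons [1000,1200],[1800,2000],
                             # CDS [1050,1150]+[1800,1900], plus strand
  expect_equal(classify_variant("1", 1100, g), "exonic")
  expect_equal(classify_variant("1", 1020, g), "UTR5")   # exon before CDS, + strand
  expect_equal(classify_variant("1", 1950, g), "UTR3")   # exon after CDS
  expect_equal(classify_variant("1", 1500, g), "intronic")
  expect_equal(classify_variant("1", 2500, g), "downstream")  # within 1 kb of TES
  expect_equal(classify_variant("1", 500, g), "upstream")
  expect_equal(classify_variant("1", 5000, g), "intergenic")
  # minus strand swaps the UTR and flank orientations
  gm_ <- toy_gene_model("-")
  expect_equal(classify_variant("1", 1020, gm_), "UTR3")
  expect_equal(classify_variant("1", 1950, gm_), "UTR5")
  expect_equal(classify_variant("1", 2500, gm_), "upstream")
  expect_equal(classify_variant("1", 500, gm_), "downstream")
  # chromosome absent from the model
  expect_equal(classify_variant("7", 1100, g), "intergenic")
})

test_that("category precedence and the combined upstream/downstream rule apply", {
  # non-coding gene
  nc <- data.frame(gene = "NC1", chrom = "1", strand = "+",
                   tx_start = 100L, tx_end = 500L,
                   exon_starts = "100,400", exon_ends = "200,500",
                   cds_starts = "", cds_ends = "")
  expect_equal(classify_variant("1", 150, nc), "ncRNA_exonic")
  expect_equal(classify_variant("1", 300, nc), "ncRNA_intronic")
  # a variant between two genes, downstream of one and upstream of the other
  two <- rbind(toy_gene_model("+"),
               transform(toy_gene_model("+"), gene = "TOY2",
                         tx_start = 3000L, tx_end = 4000L,
                         exon_starts = "3000", exon_ends = "4000",
                         cds_starts = "3100", cds_ends = "3900"))
  expect_equal(classify_variant("1", 2500, two), "upstream/downstream")
  # exonic beats an overlapping gene's intron
  both <- rbind(toy_gene_model("+"), nc)
  both$tx_start[2] <- 900L; both$tx_end[2] <- 1500L
  both$exon_starts[2] <- "900"; both$exon_ends[2] <- "1500"
  expect_equal(classify_variant("1", 1100, both), "exonic")
  # every variant gets exactly one category; counts are conserved
  set.seed(95)
  hits <- data.frame(chrom = "1", pos = sample.int(6000, 200))
  cl <- classify_variants(hits, two)
  expect_equal(nrow(cl), 200)
  expect_equal(sum(table(cl$category)), 200)
})

test_that("exonic consequences match an independent codon translation", {
  # all 576 single-base codon changes against the Biostrings genetic code
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  n_checked <- 0
  for (cod in codons) for (p in 1:3) for (b in bases) {
    if (substr(cod, p, p) == b) next
    alt <- cod
    substr(alt, p, p) <- b
    expect_equal(translate_codon(cod) == translate_codon(alt),
                 unname(gc[cod] == gc[alt]))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 576)
})

test_that("exonic_function is strand-aware and classifies indels by frame", {
  # plus-strand gene, CDS 1050-1150 + 1800-1900 (202 bp -> trim to 201 = 67 codons)
  g <- data.frame(gene = "T", chrom = "1", strand = "+",
                  tx_start = 1000L, tx_end = 2000L,
                  exon_starts = "1000,1800", exon_ends = "1200,2000",
                  cds_starts = "1050,1800", cds_ends = "1150,1899")
  set.seed(7)
  cds_len <- (1150 - 1050 + 1) + (1899 - 1800 + 1)
  expect_equal(cds_len %% 3, 0)
  cds <- paste(sample(c("A", "C", "G", "T"), cds_len, TRUE), collapse = "")
  # force a known codon at the start: AAA
  substr(cds, 1, 3) <- "AAA"
  ref1 <- substr(cds, 3, 3)          # third position of codon 1 (genomic 1052)
  expect_equal(exonic_function(1052, "A", "G", g, cds), "synonymous")  # AAA->AAG
  expect_equal(exonic_function(1050, "A", "G", g, cds), "nonsynonymous") # AAA->GAA
  expect_equal(exonic_function(1052, "A", "AG", g, cds), "frameshift")
  expect_equal(exonic_function(1052, "AGGG", "A", g, cds), "nonframeshift")
  expect_equal(exonic_function(1500, "A", "G", g, cds), "unknown")  # intronic

  # minus strand: genomic REF is the complement of the CDS base
  gm_ <- g; gm_$strand <- "-"
  # CDS on minus strand: genomic 1899 is CDS position 1
  substr(cds, 1, 3) <- "AAA"
  # genomic base at CDS pos 1 is revcomp("A") = "T"
  expect_equal(exonic_function(1899, "T", "C", gm_, cds), "nonsynonymous") # AAA->GAA
  expect_equal(exonic_function(1897, "T", "C", gm_, cds), "synonymous")    # AAA->AAG

  # CDS length not divisible by 3 warns and returns unknown
  gbad <- g; gbad$cds_ends <- "1150,1900"
  expect_warning(res <- exonic_function(1052, "A", "G", gbad,
                                        paste0(cds, "GG")), "multiple of 3")
  expect_equal(res, "unknown")
})

test_that("regulatory intersection follows BED half-open semantics", {
  els <- data.frame(chrom = "1", start = c(100L, 300L), end = c(200L, 400L),
                    element_id = c("E1", "E2"),
                    connected = c("GENEA,GENEB", "GENEB"))
  els$length_bp <- els$end - els$start
  hits <- data.frame(chrom = "1", pos = c(100L, 101L, 150L, 200L, 350L),
                     key = paste0("v", 1:5))
  res <- intersect_regulatory(hits, els)
  e1 <- res$per_element[res$per_element$element_id == "E1", ]
  # pos 100 -> 0-based 99 < 100: NO overlap; 101 and 150 overlap; 200 -> 199 < 200 overlaps
  expect_equal(e1$n_hits, 3)
  expect_setequal(strsplit(e1$hits, ",")[[1]], c("v2", "v3", "v4"))
  # fan-out: E1's hits appear under both connected features
  pf <- res$per_feature
  expect_equal(pf$n_hits[pf$feature == "GENEA"], 3)
  expect_setequal(strsplit(pf$hits[pf$feature == "GENEB"], ",")[[1]],
                  c("v2", "v3", "v4", "v5"))
  expect_equal(pf$n_elements[pf$feature == "GENEB"], 2)
  # per-feature union equals the union over supporting elements
  expect_setequal(unlist(strsplit(pf$hits[pf$feature == "GENEB"], ",")),
                  union(strsplit(e1$hits, ",")[[1]],
                        strsplit(res$per_element$hits[2], ",")[[1]]))
})

test_that("regulatory intersection equals brute-force overlap on random toys", {
  set.seed(97)
  for (rep_ in 1:100) {
    n_el <- sample(1:6, 1); n_hit <- sample(1:15, 1)
    start0 <- sort(sample.int(900, n_el))
    els <- data.frame(chrom = "1", start = start0,
                      end = start0 + sample(1:80, n_el, TRUE),
                      element_id = paste0("E", seq_len(n_el)),
                      connected = "F")
    els$length_bp <- els$end - els$start
    hits <- data.frame(chrom = "1", pos = sample.int(1000, n_hit),
                       key = paste0("v", seq_len(n_hit)))
    res <- intersect_regulatory(hits, els)
    brute <- oracle_bed_overlap(hits$pos, els$start, els$end)
    expect_equal(res$per_element$n_hits, unname(colSums(brute)))
  }
})

test_that("regulatory density reproduces the printed per-element arithmetic", {
  pe <- data.frame(element_id = c("GH20J024425", "GH02J143479", "Z"),
                   chrom = "x", start = 0L, end = 1L,
                   length_bp = c(1999L, 4983L, 1000L),
                   connected = "F", n_hits = c(3L, 1L, 0L), hits = "")
  d <- regulatory_density(pe, top_k = 1)
  expect_equal(round(d$density[d$element_id == "GH20J024425"], 4), 1.5008)
  expect_equal(round(d$density[d$element_id == "GH02J143479"], 4), 0.2007)
  expect_false("Z" %in% d$element_id)
  expect_equal(d$top, c(TRUE, FALSE))
  dz <- regulatory_density(pe, keep_zeros = TRUE)
  expect_equal(dz$density[dz$element_id == "Z"], 0)
})

test_that("ancestry cross-reference filters posteriors and averages per-hit proportions", {
  tracts <- data.frame(
    sample = rep(c("s1", "s2"), each = 2),
    hap = rep(1:2, 2), chrom = "1", start = 1L, end = 1000L,
    ancestry = c("NAT", "NAT", "NAT", "EUR"),
    posterior = c(0.99, 0.95, 0.92, 0.97))
  hits <- data.frame(chrom = "1", pos = c(100L, 500L))
  res <- ancestry_crossref(hits, tracts, min_posterior = 0.9)
  expect_equal(unname(res$per_hit[, "NAT"]), c(0.75, 0.75))  # 3 of 4 haplotypes
  expect_equal(res$summary$mean[res$summary$ancestry == "NAT"], 0.75)
  expect_equal(res$summary$sd[res$summary$ancestry == "NAT"], 0)

  # a tract below the threshold is discarded
  tracts$posterior[4] <- 0.85
  res2 <- ancestry_crossref(hits, tracts, min_posterior = 0.9)
  expect_equal(unname(res2$per_hit[, "NAT"]), c(1, 1))
  expect_equal(unname(res2$per_hit$n_assigned), c(3, 3))

  # all haplotypes one ancestry: mean 1, sd 0
  tracts$ancestry <- "NAT"; tracts$posterior <- 1
  res3 <- ancestry_crossref(hits, tracts)
  expect_equal(res3$summary$mean[res3$summary$ancestry == "NAT"], 1)
  expect_equal(res3$summary$sd[res3$summary$ancestry == "NAT"], 0)

  # a hit outside every tract is excluded and counted
  hits2 <- rbind(hits, data.frame(chrom = "2", pos = 1L))
  res4 <- ancestry_crossref(hits2, tracts)
  expect_equal(res4$n_uncovered, 1)
})

test_that("gene-model and tract readers validate and convert coordinates", {
  f <- tempfile(fileext = ".tsv")
  write.table(toy_gene_model("+"), f, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- read_gene_models(f)
  expect_equal(g$tx_start, 1000L)
  bad <- toy_gene_model("+"); bad$cds_starts <- "900"; bad$cds_ends <- "950"
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_models(f), "CDS outside exons")

  tf <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample = "s1", hap = 1L, chrom = "1",
                         start = 100L, end = 200L, ancestry = "NAT",
                         posterior = 0.99),
              tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- read_tracts(tf)
  expect_equal(tr$start, 101L)                   # BED-like 0-based converted
  expect_equal(tr$end, 200L)

  ef <- tempfile(fileext = ".tsv")
  write.table(data.frame(chrom = "1", start = 99L, end = 200L,
                         element_id = "E1", connected = "G1"),
              ef, sep = "\t", quote = FALSE, row.names = FALSE)
  eb <- read_pseudo_bed(ef)
  expect_equal(eb$length_bp, 101L)
  # 1-based element table converts once to 0-based half-open
  conv <- elements_to_pseudo_bed(data.frame(chrom = "1", start = 100L, end = 200L))
  expect_equal(conv$start, 99L)
  expect_equal(conv$length_bp, 101L)
})

test_that("GFF3 gene models can stand in for the simplified table", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\ttoy\tgene\t1000\t2000\t.\t+\t.\tID=gene1;Name=TOY1",
    "1\ttoy\tmRNA\t1000\t2000\t.\t+\t.\tID=tx1;Parent=gene1",
    "1\ttoy\texon\t1000\t1200\t.\t+\t.\tID=ex1;Parent=tx1",
    "1\ttoy\texon\t1800\t2000\t.\t+\t.\tID=ex2;Parent=tx1",
    "1\ttoy\tCDS\t1050\t1150\t.\t+\t0\tID=cds1;Parent=tx1",
    "1\ttoy\tCDS\t1800\t1900\t.\t+\t0\tID=cds2;Parent=tx1"), f)
  g <- read_gene_models_gff3(f)
  expect_equal(g$gene, "TOY1")
  expect_equal(g$exon_starts, "1000,1800")
  expect_equal(g$cds_ends, "1150,1900")
  expect_equal(classify_variant("1", 1100, g), "exonic")
  expect_equal(classify_variant("1", 1500, g), "intronic")
})
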