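test_that("forward panels are reproducible and honour the sweep contract", {
  sw <- sweep_scenario(N = 80, s = 0.2, L = 5e4, target_freq = 0.6, seed = 5)
  p1 <- simulate_forward_panel(sw, vcf_path = f1 <- tempfile(fileext = ".vcf"))
  p2 <- simulate_forward_panel(sw, vcf_path = f2 <- tempfile(fileext = ".vcf"))
  expect_identical(readLines(f1), readLines(f2))      # byte-identical VCF
  expect_gte(p1$truth$final_freq, 0.6)
  expect_lt(p1$truth$final_freq, 1)
  expect_true(all(p1$truth$trajectory >= 0 & p1$truth$trajectory <= 1))
  expect_match(p1$truth$causal_key, "^1:")
  # the causal variant is present and polarized in the emitted matrix
  k <- match(p1$truth$causal_key, variant_key(p1$gm))
  expect_false(is.na(k))
  expect_true(p1$gm$anc_state[k] %in% c("ref", "alt"))
  # impossible conditioning errors out at the attempt cap
  hopeless <- sweep_scenario(N = 50, s = 0.001, L = 1e4, target_freq = 0.99,
                             max_gen = 30, max_attempts = 3, seed = 1)
  expect_error(simulate_forward_panel(hopeless), "attempts")
})

test_that("neutral forward panels reach mutation-drift equilibrium diversity", {
  # expected pairwise diversity per site = 4 N mu
  N <- 200; mu <- 1e-8; L <- 1e5
  pis <- vapply(1:20, function(i) {
    p <- simulate_forward_panel(sweep_scenario(N = N, s = 0, L = L, mu = mu,
                                               rec = 5e-7, seed = 100 + i))
    n2 <- 2 * length(p$gm$samples)
    f <- (rowSums(p$gm$a1) + rowSums(p$gm$a2)) / n2
    sum(2 * f * (1 - f) * n2 / (n2 - 1)) / L
  }, numeric(1))
  expect_equal(mean(pis), 4 * N * mu, tolerance = 0.25)
})

test_that("neutral forward-panel spectra are consistent with the 1/i law", {
  # a 25-diploid subsample of each 60-diploid panel: the 1/i law is the
  # coalescent limit for a sample much smaller than the population
  counts <- integer(0); n_hap <- NULL
  for (i in 1:4) {
    p <- simulate_forward_panel(sweep_scenario(N = 60, s = 0, L = 2e5,
                                               mu = 5e-7, seed = 200 + i),
                                n_sample = 25)
    man <- data.frame(sample_id = p$gm$samples, population = "p")
    daf <- derived_allele_freq(p$gm, man, "p")
    n_hap <- 2 * length(p$gm$samples)
    counts <- c(counts, round(daf * n_hap))
  }
  # pool into 10 derived-count classes to keep expected counts healthy
  cls <- cut(counts, breaks = seq(0.5, n_hap - 0.5, length.out = 11))
  probs <- diff(vapply(seq(0.5, n_hap - 0.5, length.out = 11), function(b)
    sum(1 / seq_len(floor(b))), numeric(1)))   # cumulative harmonic mass
  expect_gt(chisq.test(as.numeric(table(cls)),
                       p = probs / sum(probs))$p.value, 0.01)
})

test_that("sweep panels lose diversity near the sweep site relative to the edges", {
  dips <- vapply(1:3, function(i) {
    sw <- sweep_scenario(N = 150, s = 0.5, L = 2e5, target_freq = 0.9,
                         seed = 300 + i)
    p <- simulate_forward_panel(sw)
    f <- (rowSums(p$gm$a1) + rowSums(p$gm$a2)) / (2 * length(p$gm$samples))
    het <- 2 * f * (1 - f)
    centre <- abs(p$gm$pos - sw$sweep_pos) < 2e4
    edge <- p$gm$pos < 4e4 | p$gm$pos > 1.6e5
    sum(het[centre]) / sum(centre) - sum(het[edge]) / sum(edge)
  }, numeric(1))
  expect_lt(mean(dips), 0)
})

test_that("three-population datasets have the requested structure and pass the validators", {
  ds <- cached_small_dataset()
  expect_setequal(unique(ds$manifest$population),
                  c("focal", "ingroup", "outgroup"))
  expect_equal(as.numeric(table(ds$manifest$population)[c("outgroup", "ingroup", "focal")]),
               c(15, 15, 20))
  expect_null(ds$truth)
  # round-trip through the emitted files
  dir <- tempfile()
  paths <- write_dataset(ds, dir)
  gm <- read_vcf(paths["vcf"])
  man <- read_manifest(paths["manifest"])
  anc <- read_ancestral(paths["ancestral"])
  expect_equal(n_sites(gm), n_sites(ds$gm))
  expect_identical(man$sample_id, ds$manifest$sample_id)
  # re-polarizing from the emitted table reproduces the generator's truth
  gp <- polarize(gm, anc)
  expect_identical(gp$anc_state, ds$gm$anc_state)
  # filters accept the dataset (everything segregates, fully called)
  res <- filter_sites(gm, max_missing_frac = 0, min_maf = 0)
  expect_equal(n_sites(res$gm), n_sites(gm))
})

test_that("sweep datasets carry a linked panel, truth record and deterministic layout", {
  sw <- sweep_scenario(N = 100, s = 0.3, L = 5e4, target_freq = 0.7, seed = 8)
  mod <- default_three_pop_model(N_focal = 100, N_ref = 300, N_anc = 200,
                                 t_in = 80, t_out = 160)
  ds <- make_three_pop_dataset(model = mod, sweep = sw, seed = 8,
                               n_background = 300,
                               background_chroms = c("1", "2"),
                               sample_config = c(outgroup = 20, ingroup = 20,
                                                 focal = 30))
  expect_true(sum(ds$gm$chrom == "22") > 10)
  expect_false(is.na(ds$truth$causal_key))
  k <- match(ds$truth$causal_key, variant_key(ds$gm))
  man <- ds$manifest
  daf <- derived_allele_freq(ds$gm, man, "focal")[k]
  expect_gte(daf + 0.15, ds$truth$final_freq)     # sampled frequency near truth
  expect_equal(derived_allele_freq(ds$gm, man, "ingroup")[k], 0)
  expect_equal(derived_allele_freq(ds$gm, man, "outgroup")[k], 0)
  ds2 <- make_three_pop_dataset(model = mod, sweep = sw, seed = 8,
                                n_background = 300,
                                background_chroms = c("1", "2"),
                                sample_config = c(outgroup = 20, ingroup = 20,
                                                  focal = 30))
  expect_identical(variant_key(ds$gm), variant_key(ds2$gm))
})

test_that("toy annotations are structurally valid and close the ancestry loop", {
  toy <- make_toy_annotations(seed = 3, genome_length = 1e5, n_genes = 3,
                              n_elements = 5, samples = paste0("s", 1:4))
  g <- toy$gene_model
  expect_equal(nrow(g), 3)
  o <- order(g$tx_start)
  expect_true(all(g$tx_start[o][-1] > g$tx_end[o][-3]))   # non-overlapping
  for (i in 1:3) expect_silent(sweepscan:::gene_intervals(g[i, ]))
  expect_true(all(nzchar(toy$elements$connected)))
  expect_true(all(toy$elements$end > toy$elements$start))
  # tracts tile each haplotype without overlap
  tr <- toy$tracts
  for (key in unique(paste(tr$sample, tr$hap))) {
    t1 <- tr[paste(tr$sample, tr$hap) == key, ]
    t1 <- t1[order(t1$start), ]
    expect_true(all(t1$start[-1] > t1$end[-nrow(t1)]))
    expect_equal(t1$start[1], 1)
    expect_equal(max(t1$end), 1e5)
  }
  expect_error(make_toy_annotations(seed = 1, genome_length = 5000, n_genes = 10),
               "pack")

  # pure-NAT tracts give ancestry proportion exactly 1 at any hit
  nat <- make_toy_annotations(seed = 4, ancestry_probs = c(NAT = 1),
                              posterior_noise = 0)
  hits <- data.frame(chrom = "1", pos = c(5000L, 50000L))
  res <- ancestry_crossref(hits, nat$tracts)
  expect_equal(res$summary$mean, 1)
  expect_equal(res$summary$sd, 0)

  # a 0.75 NAT mixture gives per-hit proportions near 0.75 (binomial error)
  mix <- make_toy_annotations(seed = 6, ancestry_probs = c(NAT = 0.75, EUR = 0.25),
                              posterior_noise = 0, samples = paste0("s", 1:60))
  resm <- ancestry_crossref(data.frame(chrom = "1", pos = 50000L), mix$tracts)
  p_nat <- resm$summary$mean[resm$summary$ancestry == "NAT"]
  expect_lt(abs(p_nat - 0.75), 3 * sqrt(0.75 * 0.25 / 120))
})

test_that("an implanted strong sweep is recovered end to end by the cross-referenced scan", {
  sw <- sweep_scenario(s = 0.5, L = 2e5, mu = 2.5e-7, seed = 77)
  ds <- make_three_pop_dataset(sweep = sw, seed = 77)
  null <- null_pbs_distribution(ds$model, 2500,
                                c(outgroup = 100, ingroup = 66, focal = 152),
                                "focal", "ingroup", "outgroup", seed = 78)
  sc <- selection_scan(ds$gm, ds$manifest, "focal", "ingroup", "outgroup",
                       null = null)
  k <- match(ds$truth$causal_key,
             with(sc$table, paste(chrom, pos, ref, alt, sep = ":")))
  expect_true(sc$table$in_top_pbs[k])
  expect_lt(sc$table$pbs_p[k], 0.011)
  # the haplotype statistic is extreme at the causal site relative to the scan
  expect_gt(abs(sc$table$ihs_raw[k]),
            quantile(abs(sc$table$ihs_raw), 0.95, na.rm = TRUE))
})
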