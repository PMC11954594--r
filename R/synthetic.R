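#' Default three-population demographic model
#'
#' Desk-scale focal/ingroup/outgroup topology mirroring a recent-divergence,
#' founder-bottleneck history: a moderately sized ancestral population, two
#' reference populations that expand after their splits, and a focal
#' population founded by a strong bottleneck at its divergence and held at
#' founder size since (the recent focal bottleneck is the least-characterized
#' part of such histories, so the default keeps it maximal).  The focal
#' divergence time defaults to the typical duration of the default
#' conditioned sweep, so an implanted sweep spans the focal branch.
#'
#' @param N_focal focal diploid size (default 200).
#' @param N_ref ingroup/outgroup diploid size after expansion (default 1000).
#' @param N_anc ancestral diploid size (default 500).
#' @param t_in focal-ingroup divergence, generations (default 250, the typical
#'   duration of the default conditioned sweep).
#' @param t_out ingroup-outgroup divergence, generations (default 500).
#' @return a [demographic_model()].
#' @export
default_three_pop_model <- function(N_focal = 200, N_ref = 1000, N_anc = 500,
                                    t_in = 250, t_out = 500) {
  demographic_model(
    sizes = c(outgroup = N_ref, ingroup = N_ref, focal = N_focal),
    divergences = data.frame(time = c(t_in, t_out),
                             child = c("focal", "ingroup"),
                             parent = c("ingroup", "outgroup")),
    size_changes = data.frame(population = c("ingroup", "outgroup"),
                              time = c(t_in, t_out),
                              size = c(N_anc, N_anc)))
}

## model geometry helpers for the forward mirror
model_times <- function(model) {
  dv <- model$divergences
  list(t_in = dv$time[dv$child == "focal"],
       t_out = dv$time[dv$child == "ingroup"])
}

#' Generate a complete synthetic three-population dataset
#'
#' Every input the scan pipeline needs, with known truth: unlinked neutral
#' background variants simulated under the coalescent `model`, plus (when a
#' [sweep_scenario()] is given) a linked sweep region simulated forward in
#' time with population splits mirroring the model's divergence times.  The
#' forward mirror burns the founder population in to mutation-drift
#' equilibrium, splits the outgroup (expanding it to the model's reference
#' size), later splits ingroup and focal, and introduces the selected
#' mutation in the focal population at its split, sampling at the first
#' generation the derived allele reaches the target frequency (duration `D`);
#' the ingroup and outgroup are sampled after evolving `D` and
#' `t_out - t_in + D` post-split generations respectively, so all populations
#' are sampled at the same present.
#'
#' @param model a [demographic_model()] with populations named `focal`,
#'   `ingroup`, `outgroup` (default [default_three_pop_model()]).
#' @param sweep a [sweep_scenario()] or `NULL` for a fully neutral dataset.
#'   `sweep$N` must equal the model's focal size.
#' @param seed integer master seed; all stages draw from named substreams.
#' @param sample_config named haplotype counts (even) per population; the
#'   default mirrors a 50/33/76-individual study design.
#' @param n_background number of unlinked background SNPs.
#' @param background_chroms chromosome labels over which background SNPs are
#'   spread (spacing uniform in `spacing`).
#' @param sweep_chrom chromosome label of the sweep region.
#' @param spacing range (bp) of inter-SNP background spacing.
#' @return list with `gm`, `manifest`, `ancestral`, `truth` (`NULL` without a
#'   sweep), and the `model`.
#' @export
make_three_pop_dataset <- function(model = default_three_pop_model(),
                                   sweep = NULL, seed = 1L,
                                   sample_config = c(outgroup = 100,
                                                     ingroup = 66,
                                                     focal = 152),
                                   n_background = 4000,
                                   background_chroms = as.character(1:8),
                                   sweep_chrom = "22",
                                   spacing = c(1000, 3000)) {
  stopifnot(all(c("focal", "ingroup", "outgroup") %in% model$populations),
            !(sweep_chrom %in% background_chroms))
  set.seed(substream_seed(seed, "background_positions"))
  per <- diff(round(seq(0, n_background, length.out = length(background_chroms) + 1)))
  chrom <- rep(background_chroms, per)
  positions <- unlist(lapply(per, function(k)
    cumsum(round(stats::runif(k, spacing[1], spacing[2])))))
  bg <- simulate_snp_sites(model, n_background, sample_config,
                           seed = substream_seed(seed, "background_sites"),
                           chrom = chrom, positions = positions)
  anc_bg <- ancestral_of(bg$gm)
  if (is.null(sweep)) {
    return(list(gm = bg$gm, manifest = bg$manifest, ancestral = anc_bg,
                truth = NULL, model = model))
  }
  tm <- model_times(model)
  N_anc <- pop_size_at(model, model$root, tm$t_out + 1)
  N_in <- model$sizes[["ingroup"]]
  N_out <- model$sizes[["outgroup"]]
  if (sweep$N != model$sizes[["focal"]])
    warning("sweep scenario N differs from the model's focal size")
  mu <- sweep$mu; rec <- sweep$rec; L <- sweep$L
  N_focal <- sweep$N
  set.seed(substream_seed(seed, "burnin"))
  anc1 <- wf_evolve(wf_state(N_anc), 10 * N_anc, mu, rec, L)
  set.seed(substream_seed(seed, "ancestor2"))
  anc2 <- wf_generation(anc1, mu, rec, L, drop_fixed = FALSE)
  if (tm$t_out - tm$t_in > 1)
    anc2 <- wf_evolve(anc2, tm$t_out - tm$t_in - 1, mu, rec, L,
                      drop_fixed = FALSE)
  scen <- sweep
  while (scen$sweep_pos %in% anc2$pos) scen$sweep_pos <- scen$sweep_pos + 1L
  res <- NULL
  for (attempt in seq_len(scen$max_attempts)) {
    set.seed(substream_seed(seed, paste0("sweep", attempt)))
    # founder bottleneck: the focal population is drawn at its own size from
    # the ancestor, then the selected mutation enters on one haplotype
    focal0 <- wf_generation(anc2, mu, rec, L, N_off = N_focal,
                            drop_fixed = FALSE)
    res <- wf_sweep_attempt(focal0, scen, drop_fixed = FALSE)
    if (!is.null(res)) break
  }
  if (is.null(res))
    stop("sweep never reached target frequency in ", scen$max_attempts,
         " attempts; increase s or lower target_freq")
  D <- res$generations
  focal_state <- res$state
  set.seed(substream_seed(seed, "ingroup"))
  in_state <- wf_generation(anc2, mu, rec, L, N_off = N_in, drop_fixed = FALSE)
  in_state <- wf_evolve(in_state, D, mu, rec, L, drop_fixed = FALSE)
  set.seed(substream_seed(seed, "outgroup"))
  out_state <- wf_generation(anc1, mu, rec, L, N_off = N_out,
                             drop_fixed = FALSE)
  out_state <- wf_evolve(out_state, tm$t_out - tm$t_in + D, mu, rec, L,
                         drop_fixed = FALSE)
  set.seed(substream_seed(seed, "panel_emit"))
  states <- list(outgroup = out_state, ingroup = in_state, focal = focal_state)
  all_pos <- sort(unique(c(out_state$pos, in_state$pos, focal_state$pos)))
  blocks <- lapply(names(sample_config), function(p) {
    st <- states[[p]]
    n_hap <- sample_config[[p]]
    ind <- sample.int(st$N, n_hap / 2)
    rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    h <- matrix(0L, n_hap, length(all_pos))      # absent site = ancestral
    h[, match(st$pos, all_pos)] <- st$haps[rows, , drop = FALSE]
    h
  })
  haps <- do.call(rbind, blocks)
  seg <- colSums(haps) > 0 & colSums(haps) < nrow(haps)
  panel <- panel_to_gm(haps[, seg, drop = FALSE], all_pos[seg], sweep_chrom,
                       bg$manifest$sample_id)
  truth <- list(sweep_pos = scen$sweep_pos, trajectory = res$trajectory,
                final_freq = wf_freq(focal_state, scen$sweep_pos),
                sweep_duration = D, attempts = attempt,
                causal_key = NA_character_)
  k <- which(panel$gm$pos == scen$sweep_pos)
  if (length(k)) truth$causal_key <- variant_key(panel$gm)[k]
  gm <- rbind_gm(bg$gm, panel$gm)
  list(gm = gm, manifest = bg$manifest,
       ancestral = rbind(anc_bg, panel$ancestral),
       truth = truth, model = model)
}

## ancestral table of a polarized genotype matrix
ancestral_of <- function(gm) {
  known <- gm$anc_state != "unknown"
  data.frame(chrom = gm$chrom[known], pos = gm$pos[known],
             ancestral = ifelse(gm$anc_state[known] == "ref",
                                gm$ref[known], gm$alt[known]),
             stringsAsFactors = FALSE)
}

## stack two genotype matrices over the same samples (disjoint chromosomes)
rbind_gm <- function(g1, g2) {
  stopifnot(identical(g1$samples, g2$samples),
            !any(g2$chrom %in% g1$chrom))
  genotype_matrix(c(g1$chrom, g2$chrom), c(g1$pos, g2$pos),
                  c(g1$ref, g2$ref), c(g1$alt, g2$alt),
                  rbind(g1$a1, g2$a1), rbind(g1$a2, g2$a2),
                  c(g1$phased, g2$phased), g1$samples,
                  c(g1$anc_state, g2$anc_state))
}

#' Toy gene models, regulatory elements and ancestry tracts
#'
#' Random but structurally valid annotation fixtures: non-overlapping genes
#' with exon/CDS structure (a fraction are non-coding), regulatory elements
#' each connected to 1-3 features, and local-ancestry tracts tiling every
#' haplotype of every sample with a configurable ancestry mixture and
#' posterior noise.
#'
#' @param seed integer seed.
#' @param genome_length chromosome length in bp.
#' @param n_genes,n_elements how many genes / regulatory elements.
#' @param chrom chromosome label.
#' @param samples sample ids for the tract file.
#' @param ancestry_probs named mixture weights over ancestry labels.
#' @param posterior_noise sd of the downward posterior noise (0 = all tracts
#'   posterior 1).
#' @param coding_frac fraction of genes given a CDS.
#' @return list with `gene_model`, `elements` (0-based half-open pseudo-BED
#'   data.frame) and `tracts`.
#' @export
make_toy_annotations <- function(seed = 1L, genome_length = 1e5, n_genes = 3,
                                 n_elements = 5, chrom = "1",
                                 samples = paste0("s", 1:4),
                                 ancestry_probs = c(NAT = 0.9, EUR = 0.07,
                                                    AFR = 0.03),
                                 posterior_noise = 0.03,
                                 coding_frac = 0.7) {
  set.seed(substream_seed(seed, "annotations"))
  stopifnot(n_genes >= 0, n_elements >= 0)
  lens <- if (n_genes) round(stats::runif(n_genes, 2000, 8000)) else integer(0)
  if (sum(lens) + (n_genes + 1) * 500 > genome_length)
    stop("cannot pack ", n_genes, " genes into ", genome_length, " bp")
  slack <- genome_length - sum(lens)
  gaps <- if (n_genes) as.vector(stats::rmultinom(1, slack - 500, rep(1, n_genes))) + 250
          else integer(0)
  tx_start <- cumsum(gaps) + cumsum(c(0, lens[-length(lens)]))
  tx_end <- tx_start + lens - 1
  gene_rows <- lapply(seq_len(n_genes), function(i) {
    n_ex <- sample(1:3, 1)
    cuts <- sort(sample(seq(tx_start[i] + 200, tx_end[i] - 200, by = 1),
                        2 * (n_ex - 1)))
    ex_s <- c(tx_start[i], cuts[seq_len(n_ex - 1) * 2])
    ex_e <- c(cuts[seq_len(n_ex - 1) * 2 - 1], tx_end[i])
    coding <- stats::runif(1) < coding_frac
    cds_s <- cds_e <- integer(0)
    if (coding) {
      c_lo <- ex_s[1] + sample(20:100, 1)
      c_hi <- ex_e[n_ex] - sample(20:100, 1)
      cds_s <- pmax(ex_s, c_lo); cds_e <- pmin(ex_e, c_hi)
      keep <- cds_s <= cds_e
      cds_s <- cds_s[keep]; cds_e <- cds_e[keep]
      extra <- sum(cds_e - cds_s + 1) %% 3        # keep CDS a codon multiple
      if (extra > 0) cds_e[length(cds_e)] <- cds_e[length(cds_e)] - extra
      keep <- cds_s <= cds_e
      cds_s <- cds_s[keep]; cds_e <- cds_e[keep]
    }
    data.frame(gene = sprintf("GENE%02d", i), chrom = chrom,
               strand = sample(c("+", "-"), 1),
               tx_start = tx_start[i], tx_end = tx_end[i],
               exon_starts = paste(ex_s, collapse = ","),
               exon_ends = paste(ex_e, collapse = ","),
               cds_starts = paste(cds_s, collapse = ","),
               cds_ends = paste(cds_e, collapse = ","),
               stringsAsFactors = FALSE)
  })
  gene_model <- if (n_genes) do.call(rbind, gene_rows) else
    data.frame(gene = character(0), chrom = character(0), strand = character(0),
               tx_start = integer(0), tx_end = integer(0),
               exon_starts = character(0), exon_ends = character(0),
               cds_starts = character(0), cds_ends = character(0))
  features <- c(gene_model$gene, paste0("lnc-TOY-", seq_len(max(1, n_genes))))
  el_len <- if (n_elements) round(stats::runif(n_elements, 500, 5000)) else integer(0)
  el_start0 <- if (n_elements)
    sort(sample.int(genome_length - max(el_len, 0) - 1, n_elements)) else integer(0)
  elements <- data.frame(
    chrom = rep(chrom, n_elements), start = el_start0,
    end = el_start0 + el_len,
    element_id = sprintf("GH%02dJ%06d",
                         ifelse(is.na(suppressWarnings(as.integer(chrom))), 0L,
                                suppressWarnings(as.integer(chrom))) %% 100,
                         el_start0 %/% 100 + 1),
    connected = vapply(seq_len(n_elements), function(i)
      paste(sample(features, sample(1:3, 1)), collapse = ","), ""),
    stringsAsFactors = FALSE)
  tr <- list()
  labels <- names(ancestry_probs)
  for (s in samples) for (hp in 1:2) {
    start <- 1
    while (start <= genome_length) {
      len <- round(stats::runif(1, 15000, 40000))
      end <- min(start + len - 1, genome_length)
      post <- 1 - abs(stats::rnorm(1, 0, posterior_noise))
      tr[[length(tr) + 1]] <- data.frame(
        sample = s, hap = hp, chrom = chrom, start = start, end = end,
        ancestry = sample(labels, 1, prob = ancestry_probs),
        posterior = round(max(0.5, min(1, post)), 4),
        stringsAsFactors = FALSE)
      start <- end + 1
    }
  }
  list(gene_model = gene_model, elements = elements,
       tracts = do.call(rbind, tr))
}

#' Write a synthetic dataset to disk
#'
#' Emits the pipeline's external file formats: phased VCF, manifest TSV,
#' ancestral-allele TSV and (when present) the sweep truth record as JSON.
#'
#' @param dataset output of [make_three_pop_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "panel.vcf"),
             manifest = file.path(dir, "manifest.tsv"),
             ancestral = file.path(dir, "ancestral.tsv"))
  write_vcf(dataset$gm, paths["vcf"])
  write_manifest(dataset$manifest, paths["manifest"])
  write_ancestral(dataset$ancestral, paths["ancestral"])
  if (!is.null(dataset$truth)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("writing the truth record requires jsonlite")
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    jsonlite::write_json(dataset$truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}
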