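#' Sweep scenario for the forward simulator
#'
#' Parameters of a forward Wright-Fisher diploid simulation with an additive
#' selective sweep: burn-in to mutation-drift equilibrium, introduction of a
#' single selected mutation, and conditioning on the derived allele reaching a
#' target frequency.
#'
#' @param N diploid population size.
#' @param s selection coefficient (fitnesses 1, 1 + hs, 1 + s by derived
#'   allele count); `s = 0` gives a neutral panel.
#' @param h dominance coefficient, default 0.5 (additive).
#' @param L sequence length in bp.
#' @param mu per-site per-generation mutation rate.
#' @param rec per-bp per-generation recombination (crossover) rate.
#' @param sweep_pos physical position of the selected mutation (default `L/2`).
#' @param target_freq conditioning target: the run succeeds when the derived
#'   allele frequency first reaches this value (sampling happens immediately,
#'   while the swept haplotypes are longest).
#' @param burn_in burn-in generations, default `10 * N`.
#' @param max_gen cap on post-introduction generations per attempt.
#' @param max_attempts restart cap before erroring.
#' @param seed integer seed; every attempt uses a derived substream.
#' @return object of class `sweep_scenario`.
#' @export
sweep_scenario <- function(N = 200, s = 0.05, h = 0.5, L = 1e5, mu = 5e-7,
                           rec = 1e-6, sweep_pos = round(L / 2),
                           target_freq = 0.8, burn_in = 10 * N,
                           max_gen = max(1000, round(60 / max(s, 1e-3))),
                           max_attempts = 500, seed = 1L) {
  stopifnot(s >= 0, s <= 1, target_freq > 0, target_freq <= 1, L >= 1,
            N >= 2, mu >= 0, rec >= 0)
  structure(list(N = N, s = s, h = h, L = L, mu = mu, rec = rec,
                 sweep_pos = sweep_pos, target_freq = target_freq,
                 burn_in = burn_in, max_gen = max_gen,
                 max_attempts = max_attempts, seed = as.integer(seed)),
            class = "sweep_scenario")
}

## deterministic substream seed below 2^31, derived from (seed, name)
substream_seed <- function(seed, name) {
  v <- utf8ToInt(name)
  as.integer((as.numeric(seed) * 48271 + sum(v * seq_along(v)) * 7919) %%
               2147483629)
}

## population state: integer 0/1 matrix (2N haplotypes x sites) + positions
wf_state <- function(N) list(haps = matrix(0L, 2 * N, 0), pos = integer(0), N = N)

## one Wright-Fisher generation; sel = list(pos, s, h) or NULL.
## N_off sets the offspring population size (instantaneous resize);
## drop_fixed = FALSE keeps fixed-derived columns (needed after population
## splits, where a site fixed here may still segregate in a sister population)
wf_generation <- function(state, mu, rec, L, sel = NULL, N_off = state$N,
                          drop_fixed = TRUE) {
  N <- state$N
  haps <- state$haps
  pos <- state$pos
  w <- rep(1, N)
  if (!is.null(sel) && length(pos)) {
    k <- match(sel$pos, pos)
    if (!is.na(k)) {
      g <- haps[seq(1, 2 * N, 2), k] + haps[seq(2, 2 * N, 2), k]
      w <- c(1, 1 + sel$h * sel$s, 1 + sel$s)[g + 1]
    }
  }
  parent <- sample.int(N, 2 * N_off, replace = TRUE, prob = w)
  ncx <- stats::rpois(2 * N_off, rec * L)
  pick <- sample.int(2, 2 * N_off, replace = TRUE)    # starting haplotype
  new <- haps[2L * parent - 2L + pick, , drop = FALSE]
  one <- which(ncx == 1L)                             # bulk of crossovers
  if (length(one) && length(pos)) {
    bp <- stats::runif(length(one), 0, L)
    other <- haps[2L * parent[one] - 2L + (3L - pick[one]), , drop = FALSE]
    m <- outer(bp, pos, `<=`)                         # tail segment swaps in
    sub <- new[one, , drop = FALSE]
    sub[m] <- other[m]
    new[one, ] <- sub
  }
  for (g in which(ncx > 1L)) {
    bp <- sort(stats::runif(ncx[g], 0, L))
    seg <- findInterval(pos, bp) %% 2L                # 0 = leading segment
    rows <- 2L * parent[g] - 2L + c(pick[g], 3L - pick[g])
    gam <- haps[rows[1], ]
    swap <- seg == 1L
    gam[swap] <- haps[rows[2], swap]
    new[g, ] <- gam
  }
  n_mut <- stats::rpois(1, 2 * N_off * mu * L)
  if (n_mut > 0) {
    mp <- sample.int(L, n_mut)
    mp <- setdiff(unique(mp), pos)
    if (length(mp)) {
      add <- matrix(0L, 2 * N_off, length(mp))
      add[cbind(sample.int(2 * N_off, length(mp), replace = TRUE),
                seq_along(mp))] <- 1L
      new <- cbind(new, add)                # unsorted; emission sorts once
      pos <- c(pos, mp)
    }
  }
  cs <- colSums(new)
  keep <- cs > 0L
  if (drop_fixed) keep <- keep & cs < 2L * N_off
  if (!is.null(sel)) keep <- keep | pos == sel$pos
  list(haps = new[, keep, drop = FALSE], pos = pos[keep], N = N_off)
}

wf_evolve <- function(state, generations, mu, rec, L, sel = NULL,
                      drop_fixed = TRUE) {
  for (i in seq_len(generations))
    state <- wf_generation(state, mu, rec, L, sel, drop_fixed = drop_fixed)
  state
}

## frequency of the derived allele at `p` (0 if the site is absent)
wf_freq <- function(state, p) {
  k <- match(p, state$pos)
  if (is.na(k)) 0 else mean(state$haps[, k])
}

## run the sweep phase from a burned-in state until target frequency
## (list(state, trajectory, generations) or NULL on loss/timeout)
wf_sweep_attempt <- function(state, scen, drop_fixed = TRUE) {
  add <- matrix(0L, 2 * state$N, 1)
  add[sample.int(2 * state$N, 1), 1] <- 1L
  state$haps <- cbind(state$haps, add)
  state$pos <- c(state$pos, scen$sweep_pos)
  sel <- list(pos = scen$sweep_pos, s = scen$s, h = scen$h)
  traj <- numeric(0)
  for (g in seq_len(scen$max_gen)) {
    state <- wf_generation(state, scen$mu, scen$rec, scen$L, sel,
                           drop_fixed = drop_fixed)
    f <- wf_freq(state, scen$sweep_pos)
    traj <- c(traj, f)
    if (f == 0) return(NULL)
    if (f >= scen$target_freq && f < 1) {
      return(list(state = state, trajectory = traj, generations = g))
    }
    if (f >= 1) return(NULL)   # fixed: no polymorphic core for haplotype stats
  }
  NULL
}

## convert a haplotype panel to a genotype matrix + ancestral table; the
## simulator knows truth, so anc_state is exact and REF/ALT orientation is
## randomized
panel_to_gm <- function(haps, pos, chrom, sample_ids) {
  stopifnot(nrow(haps) == 2 * length(sample_ids))
  o <- order(pos)                 # evolution keeps columns unsorted
  pos <- pos[o]
  haps <- haps[, o, drop = FALSE]
  m <- length(pos)
  bases <- c("A", "C", "G", "T")
  anc_base <- sample(bases, m, replace = TRUE)
  der_base <- vapply(anc_base, function(b) sample(setdiff(bases, b), 1), "")
  swap <- sample(c(TRUE, FALSE), m, replace = TRUE)
  ref <- ifelse(swap, der_base, anc_base)
  alt <- ifelse(swap, anc_base, der_base)
  allele <- t(haps)                     # sites x haplotypes
  allele[swap, ] <- 1L - allele[swap, , drop = FALSE]
  n_hap <- nrow(haps)
  a1 <- allele[, seq(1, n_hap, 2), drop = FALSE]
  a2 <- allele[, seq(2, n_hap, 2), drop = FALSE]
  gm <- genotype_matrix(rep(chrom, m), pos, ref, alt, a1, a2,
                        phased = rep(TRUE, m), samples = sample_ids,
                        anc_state = ifelse(swap, "alt", "ref"))
  list(gm = gm,
       ancestral = data.frame(chrom = rep(chrom, m), pos = pos,
                              ancestral = anc_base, stringsAsFactors = FALSE))
}

#' Forward Wright-Fisher panel with an optional selective sweep
#'
#' Simulates a single diploid population to mutation-drift equilibrium
#' (`burn_in` generations from an empty panel), then (for `s > 0`) introduces
#' the selected mutation on one haplotype and evolves under genotype fitnesses
#' `1, 1 + hs, 1 + s` with multinomial offspring sampling and Poisson
#' crossovers, restarting from the burned-in state (fresh substream) until the
#' derived allele reaches the target frequency while still polymorphic.
#' Sampling happens at first target hit.
#'
#' @param scenario a [sweep_scenario()].
#' @param n_sample number of diploid individuals to sample (default all `N`).
#' @param chrom chromosome label for the emitted records.
#' @param vcf_path,anc_path optional output paths: phased VCF and ancestral
#'   table are written when given.
#' @return list with `gm` (phased, polarized [genotype_matrix()]),
#'   `ancestral` table, and `truth` (sweep position, per-generation derived
#'   frequency trajectory, final frequency, attempts used, causal variant key,
#'   `NULL` trajectory fields when `s = 0`).
#' @export
simulate_forward_panel <- function(scenario, n_sample = scenario$N,
                                   chrom = "1", vcf_path = NULL,
                                   anc_path = NULL) {
  stopifnot(inherits(scenario, "sweep_scenario"), n_sample <= scenario$N)
  set.seed(substream_seed(scenario$seed, "burnin"))
  state <- wf_evolve(wf_state(scenario$N), scenario$burn_in,
                     scenario$mu, scenario$rec, scenario$L)
  truth <- list(sweep_pos = NA_integer_, trajectory = NULL,
                final_freq = NA_real_, attempts = 0L, causal_key = NA_character_)
  if (scenario$s > 0) {
    # if a standing neutral variant occupies the sweep position, offset the
    # selected mutation deterministically to the nearest free position
    while (scenario$sweep_pos %in% state$pos)
      scenario$sweep_pos <- scenario$sweep_pos + 1L
    res <- NULL
    for (attempt in seq_len(scenario$max_attempts)) {
      set.seed(substream_seed(scenario$seed, paste0("sweep", attempt)))
      res <- wf_sweep_attempt(state, scenario)
      if (!is.null(res)) break
    }
    if (is.null(res))
      stop("sweep never reached target frequency in ", scenario$max_attempts,
           " attempts; increase s or lower target_freq")
    state <- res$state
    truth$sweep_pos <- scenario$sweep_pos
    truth$trajectory <- res$trajectory
    truth$final_freq <- wf_freq(state, scenario$sweep_pos)
    truth$attempts <- attempt
  }
  set.seed(substream_seed(scenario$seed, "emit"))
  # keep haplotype pairs intact: sample individuals, not haplotypes
  ind <- sample.int(scenario$N, n_sample)
  rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
  haps <- state$haps[rows, , drop = FALSE]
  seg <- colSums(haps) > 0 & colSums(haps) < nrow(haps)
  haps <- haps[, seg, drop = FALSE]
  pos <- state$pos[seg]
  out <- panel_to_gm(haps, pos, chrom, sprintf("panel_%03d", seq_len(n_sample)))
  if (!is.na(truth$sweep_pos)) {
    k <- which(out$gm$pos == truth$sweep_pos)
    truth$causal_key <- if (length(k)) variant_key(out$gm)[k] else NA_character_
  }
  if (!is.null(vcf_path)) write_vcf(out$gm, vcf_path)
  if (!is.null(anc_path)) write_ancestral(out$ancestral, anc_path)
  list(gm = out$gm, ancestral = out$ancestral, truth = truth)
}
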