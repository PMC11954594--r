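#' Demographic model for the coalescent null
#'
#' A piecewise-constant multi-population model: every population has a
#' present-day diploid effective size, optional backward-in-time size changes
#' (which express bottlenecks), and divergence events that merge a child
#' population into its parent looking backward.  Exactly one population (the
#' root) never merges away.  No migration.
#'
#' @param sizes named numeric vector of present-day diploid effective sizes,
#'   one per population (names are the population labels).
#' @param divergences data.frame with columns `time` (generations before
#'   present), `child`, `parent`: at `time`, lineages of `child` move into
#'   `parent`.
#' @param size_changes optional data.frame with columns `population`, `time`,
#'   `size`: from `time` generations ago backwards, the population's diploid
#'   size becomes `size` (until an older change).  A bottleneck spanning
#'   `[t0, t1]` is two rows: `(pop, t0, N_small)` and `(pop, t1, N_before)`.
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(sizes, divergences,
                              size_changes = NULL) {
  pops <- names(sizes)
  if (is.null(pops) || any(!nzchar(pops)) || anyDuplicated(pops))
    stop("sizes must be a named vector with unique population labels")
  if (any(sizes < 1)) stop("diploid sizes must be >= 1")
  divergences <- as.data.frame(divergences)
  if (nrow(divergences) != length(pops) - 1)
    stop("need exactly one divergence per non-root population")
  if (!all(c(divergences$child, divergences$parent) %in% pops))
    stop("divergence events name unknown populations")
  if (any(divergences$time < 0)) stop("divergence times must be non-negative")
  if (anyDuplicated(divergences$child))
    stop("a population can merge away only once")
  root <- setdiff(pops, divergences$child)
  if (length(root) != 1) stop("model must have exactly one root population")
  # a parent must still exist (not yet merged) when its child joins it
  merge_time <- stats::setNames(rep(Inf, length(pops)), pops)
  merge_time[divergences$child] <- divergences$time
  if (any(divergences$time > merge_time[divergences$parent]))
    stop("inconsistent event schedule: child merges after its parent is gone")
  if (!is.null(size_changes)) {
    size_changes <- as.data.frame(size_changes)
    stopifnot(all(c("population", "time", "size") %in% names(size_changes)))
    if (any(size_changes$size < 1)) stop("diploid sizes must be >= 1")
    if (any(size_changes$time < 0)) stop("size-change times must be non-negative")
    if (!all(size_changes$population %in% pops))
      stop("size changes name unknown populations")
  }
  structure(list(populations = pops, sizes = sizes,
                 divergences = divergences[order(divergences$time), ],
                 size_changes = size_changes, root = root),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic_model with", length(x$populations), "populations\n")
  for (p in x$populations)
    cat(sprintf("  %s: N = %g%s\n", p, x$sizes[[p]],
                if (p == x$root) " (root)" else ""))
  for (i in seq_len(nrow(x$divergences)))
    cat(sprintf("  t = %g: %s -> %s\n", x$divergences$time[i],
                x$divergences$child[i], x$divergences$parent[i]))
  if (!is.null(x$size_changes))
    for (i in seq_len(nrow(x$size_changes)))
      cat(sprintf("  t = %g: %s size -> %g\n", x$size_changes$time[i],
                  x$size_changes$population[i], x$size_changes$size[i]))
  invisible(x)
}

## diploid size of population `p` at time `t` (backwards)
pop_size_at <- function(model, p, t) {
  n <- model$sizes[[p]]
  sc <- model$size_changes
  if (!is.null(sc)) {
    sc <- sc[sc$population == p & sc$time <= t, , drop = FALSE]
    if (nrow(sc)) n <- sc$size[which.max(sc$time)]
  }
  n
}

## all boundary times where rates can change
model_boundaries <- function(model) {
  sort(unique(c(model$divergences$time,
                if (!is.null(model$size_changes)) model$size_changes$time)))
}

#' Simulate one coalescent genealogy under a demographic model
#'
#' Standard backward-in-time structured coalescent with piecewise-constant
#' sizes and divergence events (no migration): within each population, pairs
#' coalesce at rate `choose(k, 2) / (2N)` per generation with exponential
#' waiting times, re-drawn at every epoch boundary.
#'
#' @param model a [demographic_model()].
#' @param sample_config named integer vector: haplotypes sampled per
#'   population (present day).
#' @param seed optional integer seed (`set.seed`); `NULL` uses the current RNG
#'   state.
#' @return list with `tmrca` (generations), `total_length` (sum of branch
#'   lengths), `branches` (data list: `length` vector and `leaves`, a list of
#'   leaf-index vectors, one per branch), `leaf_population` (label per leaf
#'   haplotype) and `n_leaves`.
#' @export
simulate_genealogy <- function(model, sample_config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample_config <- sample_config[sample_config > 0]
  if (!length(sample_config)) stop("sample_config must assign >= 1 haplotype")
  if (!all(names(sample_config) %in% model$populations))
    stop("sample_config names unknown populations")
  leaf_pop <- rep(names(sample_config), sample_config)
  n <- length(leaf_pop)
  lin_pop <- match(leaf_pop, model$populations)
  leafsets <- as.list(seq_len(n))
  birth <- numeric(n)
  br_len <- numeric(0)
  br_leaves <- list()
  bounds <- model_boundaries(model)
  t <- 0
  pops <- model$populations
  div <- model$divergences
  # divergence events scheduled at time 0 apply immediately
  ev0 <- div[div$time <= 0, , drop = FALSE]
  for (e in seq_len(nrow(ev0)))
    lin_pop[lin_pop == match(ev0$child[e], pops)] <- match(ev0$parent[e], pops)
  tmrca <- 0
  while (length(leafsets) > 1) {
    k <- tabulate(lin_pop, nbins = length(pops))
    rate <- vapply(seq_along(pops), function(pi) {
      if (k[pi] < 2) return(0)
      k[pi] * (k[pi] - 1) / 2 / (2 * pop_size_at(model, pops[pi], t))
    }, numeric(1))
    total <- sum(rate)
    nxt <- bounds[bounds > t]
    nxt <- if (length(nxt)) min(nxt) else Inf
    w <- if (total > 0) stats::rexp(1, total) else Inf
    if (t + w < nxt) {
      t <- t + w
      pi <- sample.int(length(pops), 1, prob = rate)
      idx <- which(lin_pop == pi)
      pick <- idx[sample.int(length(idx), 2)]
      i <- pick[1]; j <- pick[2]
      br_len <- c(br_len, t - birth[i], t - birth[j])
      br_leaves[[length(br_leaves) + 1L]] <- leafsets[[i]]
      br_leaves[[length(br_leaves) + 1L]] <- leafsets[[j]]
      leafsets[[i]] <- c(leafsets[[i]], leafsets[[j]])
      birth[i] <- t
      leafsets[[j]] <- NULL
      lin_pop <- lin_pop[-j]
      birth <- birth[-j]
    } else {
      if (!is.finite(nxt)) stop("coalescent cannot complete: disconnected model")
      t <- nxt
      ev <- div[div$time == t, , drop = FALSE]
      for (e in seq_len(nrow(ev))) {
        ci <- match(ev$child[e], pops); pa <- match(ev$parent[e], pops)
        lin_pop[lin_pop == ci] <- pa
      }
    }
  }
  tmrca <- t
  list(tmrca = tmrca, total_length = sum(br_len),
       branches = list(length = br_len, leaves = br_leaves),
       leaf_population = leaf_pop, n_leaves = n)
}

#' Simulate unlinked biallelic SNP sites under a demographic model
#'
#' One independent genealogy per site; a single mutation is placed on a branch
#' chosen with probability proportional to branch length, so every site
#' segregates in the pooled sample (ascertainment: segregating SNPs).  Under
#' the default placement, genealogies contribute sites with probability
#' proportional to their total branch length, matching how a mutational
#' process samples sites and reproducing the neutral site-frequency law
#' exactly; `placement = "per_tree"` instead keeps exactly one site per
#' simulated genealogy, which slightly over-represents rare variants (short
#' trees are relatively rich in external branch).  Haplotypes are paired in
#' order into diploids within each population, and REF/ALT orientation is
#' randomized (the ancestral state is recorded in `anc_state`).
#'
#' @param model a [demographic_model()].
#' @param n_sites number of sites to simulate.
#' @param sample_config named integer vector of haplotypes per population
#'   (even counts: haplotypes are paired into diploids).
#' @param seed optional integer seed.
#' @param chrom chromosome label(s): scalar or length-`n_sites` vector.
#' @param positions optional integer positions (strictly increasing within
#'   chromosome); default `1:n_sites`.
#' @param placement `"mutation_weighted"` (default) or `"per_tree"`, see
#'   Details.
#' @return `list(gm = genotype_matrix, manifest = data.frame)`; genotypes are
#'   phased and polarized.
#' @export
simulate_snp_sites <- function(model, n_sites, sample_config, seed = NULL,
                               chrom = "1", positions = NULL,
                               placement = c("mutation_weighted", "per_tree")) {
  placement <- match.arg(placement)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_sites >= 1)
  if (any(sample_config %% 2 != 0))
    stop("haplotype counts must be even to pair into diploids")
  if (is.null(positions)) positions <- seq_len(n_sites)
  if (length(chrom) == 1) chrom <- rep(chrom, n_sites)
  stopifnot(length(positions) == n_sites, length(chrom) == n_sites)
  n_hap <- sum(sample_config)
  pops <- model$populations
  lin_pop0 <- match(rep(names(sample_config), sample_config), pops)
  steps <- lapply(pops, function(p) {
    sc <- model$size_changes
    if (!is.null(sc)) sc <- sc[sc$population == p, , drop = FALSE]
    tt <- c(0, if (!is.null(sc)) sc$time)
    vv <- c(model$sizes[[p]], if (!is.null(sc)) sc$size)
    o <- order(tt)
    list(times = tt[o], sizes = vv[o])
  })
  derived <- sim_snp_sites_cpp(
    n_sites, lin_pop0, length(pops),
    lapply(steps, `[[`, "times"), lapply(steps, `[[`, "sizes"),
    as.numeric(model$divergences$time),
    match(model$divergences$child, pops),
    match(model$divergences$parent, pops),
    model_boundaries(model), placement == "mutation_weighted")
  leaf_pop <- rep(names(sample_config), sample_config)
  sample_id <- paste0(rep(names(sample_config), sample_config / 2), "_",
                      unlist(lapply(sample_config / 2, seq_len)))
  manifest <- data.frame(sample_id = sample_id,
                         population = rep(names(sample_config), sample_config / 2),
                         stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  anc_base <- sample(bases, n_sites, replace = TRUE)
  der_base <- vapply(anc_base, function(b) sample(setdiff(bases, b), 1), "")
  swap <- sample(c(TRUE, FALSE), n_sites, replace = TRUE)  # ALT ancestral half the time
  ref <- ifelse(swap, der_base, anc_base)
  alt <- ifelse(swap, anc_base, der_base)
  anc_state <- ifelse(swap, "alt", "ref")
  allele <- derived
  allele[swap, ] <- 1L - allele[swap, ]
  odd <- seq(1, n_hap, by = 2)
  a1 <- allele[, odd, drop = FALSE]
  a2 <- allele[, odd + 1, drop = FALSE]
  gm <- genotype_matrix(chrom, positions, ref, alt, a1, a2,
                        phased = rep(TRUE, n_sites), samples = sample_id,
                        anc_state = anc_state)
  list(gm = gm, manifest = manifest)
}

#' Null PBS distribution from coalescent simulation
#'
#' Simulates unlinked neutral SNP sites under the demographic model, computes
#' per-site PBS for the focal population with [pbs_table()], and returns the
#' sorted null values.
#'
#' @param model a [demographic_model()] containing the three populations.
#' @param n_sites number of simulated sites.
#' @param sample_config named even integer vector of haplotypes per population.
#' @param focal,ingroup,outgroup population labels.
#' @param seed optional integer seed.
#' @return object of class `null_distribution`: sorted `values`, `n_sites`,
#'   `n_dropped` (undefined-PBS sites), `seed`, `sample_config` and a model
#'   `fingerprint`.
#' @export
null_pbs_distribution <- function(model, n_sites, sample_config,
                                  focal, ingroup, outgroup, seed = NULL) {
  for (p in c(focal, ingroup, outgroup))
    if (!p %in% names(sample_config) || sample_config[[p]] < 2)
      stop("sample_config must cover population '", p, "'")
  sim <- simulate_snp_sites(model, n_sites, sample_config, seed = seed)
  tab <- pbs_table(sim$gm, sim$manifest, focal, ingroup, outgroup)
  values <- sort(tab$pbs[!is.na(tab$pbs)])
  structure(list(values = values, n_sites = length(values),
                 n_dropped = sum(is.na(tab$pbs)),
                 seed = seed, sample_config = sample_config,
                 fingerprint = model_fingerprint(model)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("null_distribution:", x$n_sites, "simulated PBS values",
      sprintf("(%d dropped)\n", x$n_dropped))
  q <- stats::quantile(x$values, c(0.5, 0.95, 0.99))
  cat(sprintf("  median %.4f  q95 %.4f  q99 %.4f\n", q[1], q[2], q[3]))
  cat("  model fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

## compact deterministic fingerprint of a model's parameters
model_fingerprint <- function(model) {
  s <- paste(utils::capture.output(utils::str(unclass(model))), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

#' Empirical p-values against a simulated null
#'
#' Add-one empirical upper-tail p-value
#' `p = (1 + #\{null >= obs\}) / (M + 1)`, vectorized over observations by
#' binary search on the sorted null.
#'
#' @param null a `null_distribution` (or numeric vector of null values).
#' @param observed numeric vector of observed statistics (`NA` passes through).
#' @return numeric p-value vector.
#' @export
empirical_pvalue <- function(null, observed) {
  values <- if (inherits(null, "null_distribution")) null$values else sort(null)
  M <- length(values)
  if (!M) stop("empty null distribution")
  n_lt <- findInterval(observed, values, left.open = TRUE)  # #{null < obs}
  p <- (1 + (M - n_lt)) / (M + 1)
  p[is.na(observed)] <- NA_real_
  p
}

#' Write / read a null distribution as TSV with a metadata header
#'
#' @param null a `null_distribution`.
#' @param path output path.
#' @return `path` (write) or a `null_distribution` (read).
#' @export
write_null_distribution <- function(null, path) {
  meta <- c(paste0("# n_sites: ", null$n_sites),
            paste0("# n_dropped: ", null$n_dropped),
            paste0("# seed: ", if (is.null(null$seed)) "NA" else null$seed),
            paste0("# sample_config: ",
                   paste(names(null$sample_config), null$sample_config,
                         sep = "=", collapse = ",")),
            paste0("# fingerprint: ", null$fingerprint),
            "pbs")
  writeLines(c(meta, format(null$values, digits = 17, trim = TRUE)), path)
  invisible(path)
}

#' @rdname write_null_distribution
#' @export
read_null_distribution <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, ": "), "", grep(paste0("^# ", key, ":"), meta, value = TRUE))
  body <- lines[!grepl("^#", lines)][-1]
  sc <- strsplit(strsplit(get("sample_config"), ",")[[1]], "=")
  sample_config <- stats::setNames(as.integer(vapply(sc, `[`, "", 2)),
                                   vapply(sc, `[`, "", 1))
  structure(list(values = sort(as.numeric(body)),
                 n_sites = as.integer(get("n_sites")),
                 n_dropped = as.integer(get("n_dropped")),
                 seed = suppressWarnings(as.integer(get("seed"))),
                 sample_config = sample_config,
                 fingerprint = get("fingerprint")),
            class = "null_distribution")
}

#' Joint site frequency spectrum
#'
#' Counts sites by their derived-allele count combination across populations.
#' Unpolarized sites are excluded and counted in the `n_unpolarized`
#' attribute.  Entry `[i1, i2, ...]` (1-based) is the number of sites with
#' derived count `i1 - 1` in the first population, etc.
#'
#' @param gm a polarized [genotype_matrix()].
#' @param manifest sample manifest.
#' @param populations character vector of population labels (array axes).
#' @return k-dimensional integer array with attribute `n_unpolarized`.
#' @export
joint_sfs <- function(gm, manifest, populations) {
  stopifnot(all(populations %in% manifest$population))
  cols <- lapply(populations, function(p) pop_columns(gm, manifest, p))
  dims <- vapply(cols, function(cc) 2L * length(cc) + 1L, integer(1))
  polarized <- gm$anc_state != "unknown"
  counts <- vapply(seq_along(populations), function(k) {
    ac <- alt_allele_counts(gm, cols[[k]])
    der <- ifelse(gm$anc_state == "ref", ac$alt, ac$n - ac$alt)
    as.integer(der)
  }, integer(n_sites(gm)))
  counts <- matrix(counts, ncol = length(populations))
  arr <- array(0L, dim = dims, dimnames = NULL)
  idx <- counts[polarized, , drop = FALSE] + 1L
  for (r in seq_len(nrow(idx))) {
    pos <- matrix(idx[r, ], 1)
    arr[pos] <- arr[pos] + 1L
  }
  attr(arr, "n_unpolarized") <- sum(!polarized)
  attr(arr, "populations") <- populations
  arr
}
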