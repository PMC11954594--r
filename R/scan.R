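#' Top fraction of a p-value vector
#'
#' Marks the most significant fraction `q` of defined p-values.  The threshold
#' is the `ceiling(q * n)`-th smallest defined p-value; every variant with
#' `p <= threshold` is included, so ties at the threshold are all kept
#' (deterministic and conservative toward inclusion).
#'
#' @param pvalues numeric vector (`NA` = undefined, never significant).
#' @param q fraction in `(0, 1]`, default 0.01.
#' @return logical vector, `TRUE` where significant.
#' @export
top_fraction <- function(pvalues, q = 0.01) {
  stopifnot(q > 0, q <= 1)
  ok <- !is.na(pvalues)
  if (!any(ok)) stop("no defined p-values")
  thr <- sort(pvalues[ok])[ceiling(q * sum(ok))]
  !is.na(pvalues) & pvalues <= thr
}

#' Cross-reference two significant variant sets
#'
#' @param set_pbs,set_ihs character vectors of variant keys
#'   (`chrom:pos:ref:alt`).
#' @return list with the `intersection` and the sizes of both inputs.
#' @export
cross_reference <- function(set_pbs, set_ihs) {
  common <- intersect(set_pbs, set_ihs)
  list(intersection = common, n_pbs = length(unique(set_pbs)),
       n_ihs = length(unique(set_ihs)), n_common = length(common))
}

#' Assign hit variants to overlapping genes
#'
#' A hit is assigned to every gene whose transcription span contains its
#' position (1-based inclusive); a variant inside two overlapping genes gets
#' two rows, intergenic hits get none.
#'
#' @param hits data.frame with `chrom` and `pos` columns (extra columns are
#'   carried through).
#' @param gene_model data.frame with `gene`, `chrom`, `tx_start`, `tx_end`.
#' @return data.frame of hit rows replicated per overlapping gene, with a
#'   `gene` column.
#' @export
map_variants_to_genes <- function(hits, gene_model) {
  validate_gene_model(gene_model)
  if (!nrow(hits)) return(cbind(hits, gene = character(0)))
  hr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$pos, hits$pos))
  gr <- GenomicRanges::GRanges(gene_model$chrom,
                               IRanges::IRanges(gene_model$tx_start,
                                                gene_model$tx_end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(hr, gr))
  out <- hits[S4Vectors::queryHits(ov), , drop = FALSE]
  out$gene <- gene_model$gene[S4Vectors::subjectHits(ov)]
  rownames(out) <- NULL
  out
}

validate_gene_model <- function(gene_model) {
  need <- c("gene", "chrom", "tx_start", "tx_end")
  if (!all(need %in% names(gene_model)))
    stop("gene model needs columns: ", paste(need, collapse = ", "))
  bad <- gene_model$tx_start > gene_model$tx_end | is.na(gene_model$tx_start) |
    is.na(gene_model$tx_end)
  if (any(bad))
    stop("malformed gene record(s): ",
         paste(gene_model$gene[bad], collapse = ", "))
  invisible(gene_model)
}

#' Per-gene selection density
#'
#' Number of significant variants mapped to each gene, normalized by gene
#' length in kb, with per-gene mean statistics over the mapped hits.
#'
#' @param assignments output of [map_variants_to_genes()]; columns `pbs`,
#'   `pbs_p`, `ihs_std`, `ihs_p` are averaged per gene when present.
#' @param gene_model data.frame with `gene`, `chrom`, `tx_start`, `tx_end`.
#' @param keep_zeros keep genes with no hits (density 0)?
#' @return data.frame sorted by decreasing density: `gene`, `length_kb`,
#'   `n_hits`, `density` (hits/kb) and any mean statistic columns.
#' @export
selection_density <- function(assignments, gene_model, keep_zeros = FALSE) {
  validate_gene_model(gene_model)
  length_kb <- (gene_model$tx_end - gene_model$tx_start + 1) / 1000
  if (any(length_kb <= 0)) stop("gene lengths must be positive")
  n_hits <- as.integer(table(factor(assignments$gene,
                                    levels = gene_model$gene)))
  out <- data.frame(gene = gene_model$gene, length_kb = length_kb,
                    n_hits = n_hits, density = n_hits / length_kb,
                    stringsAsFactors = FALSE)
  for (col in intersect(c("pbs", "pbs_p", "ihs_std", "ihs_p"),
                        names(assignments))) {
    v <- if (col == "ihs_std") abs(assignments[[col]]) else assignments[[col]]
    m <- tapply(v, factor(assignments$gene, levels = gene_model$gene),
                mean, na.rm = TRUE)
    out[[paste0("mean_", if (col == "ihs_std") "abs_ihs" else col)]] <-
      as.numeric(m)
  }
  if (!keep_zeros) out <- out[out$n_hits > 0, , drop = FALSE]
  out <- out[order(-out$density, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene sets shared across populations
#'
#' Upset-style enumeration: every non-empty intersection class of the
#' per-population gene sets, each split by membership in an optional prior
#' literature gene list.
#'
#' @param gene_sets named list of character vectors (genes with
#'   cross-referenced hits, one vector per population).
#' @param prior_gene_list optional character vector of previously reported
#'   genes.
#' @return data.frame: `gene`, `class` (population names joined by `&`),
#'   `n_populations`, `in_prior`.
#' @export
shared_across_populations <- function(gene_sets, prior_gene_list = NULL) {
  stopifnot(length(gene_sets) >= 2, !is.null(names(gene_sets)))
  genes <- sort(unique(unlist(gene_sets)))
  if (!length(genes))
    return(data.frame(gene = character(0), class = character(0),
                      n_populations = integer(0), in_prior = logical(0)))
  member <- vapply(gene_sets, function(s) genes %in% s,
                   logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, names(gene_sets)))
  cls <- apply(member, 1, function(m) paste(names(gene_sets)[m], collapse = "&"))
  data.frame(gene = genes, class = cls,
             n_populations = rowSums(member),
             in_prior = genes %in% (prior_gene_list %||% character(0)),
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full per-population selection scan
#'
#' Orchestrates the scan for one focal population: per-site FST and PBS
#' against the ingroup/outgroup pair, empirical PBS p-values against a
#' coalescent null, the iHS scan over the focal population's phased
#' haplotypes, top-fraction thresholds on both p-value vectors, and the
#' cross-referenced candidate set.
#'
#' @param gm a polarized, phased [genotype_matrix()].
#' @param manifest sample manifest.
#' @param focal,ingroup,outgroup population labels.
#' @param null a `null_distribution` for PBS (from [null_pbs_distribution()]
#'   or [read_null_distribution()]); alternatively pass `model` to simulate
#'   one here.
#' @param model optional [demographic_model()] used when `null` is missing.
#' @param n_null_sites null size when simulating internally, default 10000.
#' @param q top fraction for both statistics, default 0.01 (the top 1\%).
#' @param rank_on `"pvalue"` (default) ranks both statistics by p-value;
#'   `"raw"` ranks PBS by value and iHS by |standardized score|.
#' @param maf,ehh_threshold,max_gap,bin_width,min_bin_count iHS settings, see
#'   [ihs_scan()] and [standardize_ihs()].  The scan default `bin_width = 0.1`
#'   is coarser than the genome-scale convention (0.025): bin moments are only
#'   stable with tens of cores per bin, so desk-scale scans of a few thousand
#'   cores need wider bins.  Lower it toward 0.025 for dense genome-wide data.
#' @param seed optional seed for the internal null simulation.
#' @return object of class `selection_scan`: `table` (per-variant statistics
#'   and flags), `hits` (cross-referenced variant keys), set sizes, and the
#'   inputs' summary.
#' @export
selection_scan <- function(gm, manifest, focal, ingroup, outgroup,
                           null = NULL, model = NULL, n_null_sites = 10000,
                           q = 0.01, rank_on = c("pvalue", "raw"),
                           maf = 0.05, ehh_threshold = 0.05, max_gap = 2e5,
                           bin_width = 0.1, min_bin_count = 10,
                           seed = NULL) {
  rank_on <- match.arg(rank_on)
  if (is.null(null)) {
    if (is.null(model))
      stop("provide a null distribution or a demographic model")
    counts <- table(manifest$population)
    sc <- 2L * as.integer(counts[c(outgroup, ingroup, focal)])
    names(sc) <- c(outgroup, ingroup, focal)
    null <- null_pbs_distribution(model, n_null_sites, sc,
                                  focal, ingroup, outgroup, seed = seed)
  }
  tab <- pbs_table(gm, manifest, focal, ingroup, outgroup)
  tab$pbs_p <- empirical_pvalue(null, tab$pbs)
  hm <- haplotype_matrix(gm, manifest, focal)
  iht <- standardize_ihs(ihs_scan(hm, maf = maf, ehh_threshold = ehh_threshold,
                                  max_gap = max_gap),
                         bin_width = bin_width, min_bin_count = min_bin_count)
  i <- match(paste(tab$chrom, tab$pos), paste(iht$chrom, iht$pos))
  tab$daf <- iht$daf[i]
  tab$ihs_raw <- iht$ihs_raw[i]
  tab$ihs_std <- iht$ihs_std[i]
  tab$ihs_p <- iht$pvalue[i]
  key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  if (rank_on == "pvalue") {
    tab$in_top_pbs <- top_fraction(tab$pbs_p, q)
    tab$in_top_ihs <- top_fraction(tab$ihs_p, q)
  } else {
    tab$in_top_pbs <- top_fraction(-tab$pbs, q)
    tab$in_top_ihs <- top_fraction(-abs(tab$ihs_std), q)
  }
  tab$cross_referenced <- tab$in_top_pbs & tab$in_top_ihs
  xr <- cross_reference(key[tab$in_top_pbs], key[tab$in_top_ihs])
  structure(list(table = tab, hits = xr$intersection,
                 n_top_pbs = xr$n_pbs, n_top_ihs = xr$n_ihs,
                 n_cross_referenced = xr$n_common,
                 focal = focal, ingroup = ingroup, outgroup = outgroup,
                 q = q, rank_on = rank_on, null = null),
            class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  cat("selection_scan for focal population '", x$focal, "'\n", sep = "")
  cat("  sites:", nrow(x$table),
      " | PBS defined:", sum(!is.na(x$table$pbs)),
      " | iHS scored:", sum(!is.na(x$table$ihs_std)), "\n")
  cat(sprintf("  top %.3g%% sets: PBS %d, iHS %d, cross-referenced %d\n",
              100 * x$q, x$n_top_pbs, x$n_top_ihs, x$n_cross_referenced))
  invisible(x)
}

#' @export
summary.selection_scan <- function(object, ...) {
  t <- object$table
  out <- list(
    n_sites = nrow(t),
    n_pbs_defined = sum(!is.na(t$pbs)),
    n_ihs_scored = sum(!is.na(t$ihs_std)),
    pbs_quantiles = stats::quantile(t$pbs, c(0.5, 0.95, 0.99), na.rm = TRUE),
    ihs_sd = stats::sd(t$ihs_std, na.rm = TRUE),
    n_top_pbs = object$n_top_pbs, n_top_ihs = object$n_top_ihs,
    n_cross_referenced = object$n_cross_referenced,
    hits = object$hits)
  class(out) <- "summary.selection_scan"
  out
}

#' @export
print.summary.selection_scan <- function(x, ...) {
  cat("sites:", x$n_sites, " PBS defined:", x$n_pbs_defined,
      " iHS scored:", x$n_ihs_scored, "\n")
  cat("PBS quantiles (50/95/99%):",
      paste(signif(x$pbs_quantiles, 4), collapse = " / "), "\n")
  cat("sd(iHS_std):", signif(x$ihs_sd, 4), "\n")
  cat("top sets: PBS", x$n_top_pbs, "| iHS", x$n_top_ihs,
      "| cross-referenced", x$n_cross_referenced, "\n")
  if (length(x$hits))
    cat("hits:", paste(utils::head(x$hits, 10), collapse = ", "),
        if (length(x$hits) > 10) "..." else "", "\n")
  invisible(x)
}

#' Manhattan-style plot of a selection scan
#'
#' Base-graphics plot of per-site -log10 PBS p-values with the cross-referenced
#' candidates highlighted.
#'
#' @param x a `selection_scan`.
#' @param ... passed to [plot()].
#' @export
plot.selection_scan <- function(x, ...) {
  t <- x$table
  ok <- !is.na(t$pbs_p)
  chr <- factor(t$chrom, levels = unique(t$chrom))
  xpos <- as.integer(chr) * 1e7 + t$pos %% 1e7
  plot(xpos[ok], -log10(t$pbs_p[ok]), pch = 16, cex = 0.4,
       col = c("grey40", "grey70")[1 + as.integer(chr[ok]) %% 2],
       xlab = "genome position (by chromosome)",
       ylab = expression(-log[10] ~ "PBS p-value"), ...)
  sel <- ok & t$cross_referenced
  graphics::points(xpos[sel], -log10(t$pbs_p[sel]), pch = 16, cex = 0.7,
                   col = "firebrick")
  invisible(x)
}

#' Write a per-site scan table as TSV with a parameter header
#'
#' @param scan a `selection_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# focal: ", scan$focal, "; ingroup: ", scan$ingroup,
           "; outgroup: ", scan$outgroup),
    paste0("# q: ", scan$q, "; rank_on: ", scan$rank_on,
           "; null_sites: ", scan$null$n_sites)), con)
  utils::write.table(scan$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
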