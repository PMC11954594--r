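#' Read a simplified gene-model table
#'
#' TSV with one row per gene: `gene`, `chrom`, `strand` (+/-), `tx_start`,
#' `tx_end`, `exon_starts`, `exon_ends`, `cds_starts`, `cds_ends` (comma
#' lists, 1-based inclusive; empty CDS columns mark non-coding genes).
#'
#' @param path input TSV path.
#' @return validated gene-model data.frame.
#' @export
read_gene_models <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = list(exon_starts = "character",
                                           exon_ends = "character",
                                           cds_starts = "character",
                                           cds_ends = "character"))
  need <- c("gene", "chrom", "strand", "tx_start", "tx_end",
            "exon_starts", "exon_ends", "cds_starts", "cds_ends")
  if (!all(need %in% names(g)))
    stop("gene model TSV needs columns: ", paste(need, collapse = ", "))
  g$cds_starts[is.na(g$cds_starts)] <- ""
  g$cds_ends[is.na(g$cds_ends)] <- ""
  validate_gene_model(g)
  for (i in seq_len(nrow(g))) gene_intervals(g[i, ])   # validates structure
  g
}

## parse a comma list of integers
int_list <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

## exon/CDS intervals of one gene-model row, with structural checks
gene_intervals <- function(row) {
  ex_s <- int_list(row$exon_starts); ex_e <- int_list(row$exon_ends)
  cd_s <- int_list(row$cds_starts); cd_e <- int_list(row$cds_ends)
  if (length(ex_s) != length(ex_e) || length(cd_s) != length(cd_e))
    stop("malformed gene record: ", row$gene)
  if (length(ex_s)) {
    o <- order(ex_s); ex_s <- ex_s[o]; ex_e <- ex_e[o]
    if (any(ex_s > ex_e) || any(ex_s[-1] <= ex_e[-length(ex_e)]))
      stop("exons overlap or are malformed in gene ", row$gene)
  }
  if (length(cd_s)) {
    o <- order(cd_s); cd_s <- cd_s[o]; cd_e <- cd_e[o]
    in_exon <- vapply(seq_along(cd_s), function(i)
      any(cd_s[i] >= ex_s & cd_e[i] <= ex_e), logical(1))
    if (!all(in_exon)) stop("CDS outside exons in gene ", row$gene)
  }
  list(exon_start = ex_s, exon_end = ex_e,
       cds_start = cd_s, cds_end = cd_e,
       coding = length(cd_s) > 0)
}

in_any <- function(pos, starts, ends) {
  length(starts) > 0 && any(pos >= starts & pos <= ends)
}

#' Genic category of a variant
#'
#' ANNOVAR-style precedence over all genes overlapping or flanking the
#' position: `exonic` (in CDS) > `UTR5`/`UTR3` (in exon of a coding gene,
#' outside CDS; 5' or 3' by strand) > `intronic` (inside a coding gene's span,
#' outside exons) > `ncRNA_exonic` > `ncRNA_intronic` > `upstream` /
#' `downstream` (within `flank_bp` of the TSS/TES, strand-aware; a variant
#' upstream of one gene and downstream of another gets the combined
#' `upstream/downstream`) > `intergenic`.
#'
#' @param chrom,pos variant coordinate (1-based).
#' @param gene_models gene-model data.frame ([read_gene_models()] /
#'   [make_toy_annotations()]).
#' @param flank_bp upstream/downstream flank, default 1000 bp.
#' @return single category string.
#' @export
classify_variant <- function(chrom, pos, gene_models, flank_bp = 1000) {
  g <- gene_models[gene_models$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return("intergenic")
  cats <- character(0)
  for (i in seq_len(nrow(g))) {
    row <- g[i, ]
    iv <- gene_intervals(row)
    minus <- identical(row$strand, "-")
    if (pos >= row$tx_start && pos <= row$tx_end) {
      if (iv$coding) {
        if (in_any(pos, iv$cds_start, iv$cds_end)) cats <- c(cats, "exonic")
        else if (in_any(pos, iv$exon_start, iv$exon_end)) {
          cds_lo <- min(iv$cds_start); cds_hi <- max(iv$cds_end)
          five <- if (minus) pos > cds_hi else pos < cds_lo
          cats <- c(cats, if (five) "UTR5" else "UTR3")
        } else cats <- c(cats, "intronic")
      } else {
        cats <- c(cats, if (in_any(pos, iv$exon_start, iv$exon_end))
          "ncRNA_exonic" else "ncRNA_intronic")
      }
    } else {
      tss <- if (minus) row$tx_end else row$tx_start
      tes <- if (minus) row$tx_start else row$tx_end
      before_tss <- if (minus) pos > tss else pos < tss
      after_tes <- if (minus) pos < tes else pos > tes
      if (before_tss && abs(pos - tss) <= flank_bp) cats <- c(cats, "upstream")
      if (after_tes && abs(pos - tes) <= flank_bp) cats <- c(cats, "downstream")
    }
  }
  if (!length(cats)) return("intergenic")
  order_cat <- c("exonic", "UTR5", "UTR3", "intronic", "ncRNA_exonic",
                 "ncRNA_intronic", "upstream", "downstream")
  hit <- order_cat[order_cat %in% cats]
  if (!length(hit)) return("intergenic")
  top <- hit[1]
  if (top %in% c("upstream", "downstream") &&
      all(c("upstream", "downstream") %in% cats))
    return("upstream/downstream")
  top
}

#' Tabulate genic categories for a set of variants
#'
#' @param hits data.frame with `chrom` and `pos`.
#' @inheritParams classify_variant
#' @return the input with a `category` column (one category per variant).
#' @export
classify_variants <- function(hits, gene_models, flank_bp = 1000) {
  hits$category <- vapply(seq_len(nrow(hits)), function(i)
    classify_variant(hits$chrom[i], hits$pos[i], gene_models, flank_bp), "")
  hits
}

## standard genetic code, indexed by codon
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L", CTA = "L",
  CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M", GTT = "V", GTC = "V",
  GTA = "V", GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S", CCT = "P",
  CCC = "P", CCA = "P", CCG = "P", ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
  TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E", TGT = "C",
  TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R", GGT = "G", GGC = "G", GGA = "G",
  GGG = "G")

#' Translate a codon with the standard genetic code
#' @param codon three-letter nucleotide string.
#' @return single-letter amino acid (`*` = stop), `NA` if untranslatable.
#' @export
translate_codon <- function(codon) {
  aa <- CODON_TABLE[toupper(codon)]
  unname(ifelse(is.na(aa), NA_character_, aa))
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

#' Exonic functional consequence of a variant
#'
#' For an SNV inside the CDS: translates the reference and alternate codons
#' (strand-aware) and reports `synonymous` or `nonsynonymous`.  For indels:
#' `frameshift` when the length change is not a multiple of 3, else
#' `nonframeshift`.  Untranslatable contexts give `unknown`.
#'
#' @param pos variant position (1-based genomic).
#' @param ref,alt allele strings.
#' @param gene_row one row of a gene-model data.frame (coding gene).
#' @param cds_seq the spliced CDS nucleotide sequence, 5' to 3' on the coding
#'   strand (length a multiple of 3).
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"frameshift"`,
#'   `"nonframeshift"`, `"unknown"`.
#' @export
exonic_function <- function(pos, ref, alt, gene_row, cds_seq) {
  if (nchar(ref) != nchar(alt)) {
    shift <- abs(nchar(ref) - nchar(alt)) %% 3
    return(if (shift != 0) "frameshift" else "nonframeshift")
  }
  if (nchar(ref) != 1) return("unknown")
  iv <- gene_intervals(gene_row)
  if (!iv$coding || !in_any(pos, iv$cds_start, iv$cds_end)) return("unknown")
  cds_pos_all <- unlist(mapply(seq, iv$cds_start, iv$cds_end,
                               SIMPLIFY = FALSE))
  minus <- identical(gene_row$strand, "-")
  if (minus) cds_pos_all <- rev(cds_pos_all)
  idx <- match(pos, cds_pos_all)            # 1-based position within the CDS
  cds_seq <- toupper(cds_seq)
  if (is.na(idx) || nchar(cds_seq) < length(cds_pos_all)) return("unknown")
  if (nchar(cds_seq) %% 3 != 0) {
    warning("CDS length of ", gene_row$gene, " is not a multiple of 3")
    return("unknown")
  }
  ref_c <- toupper(ref); alt_c <- toupper(alt)
  if (minus) { ref_c <- revcomp(ref_c); alt_c <- revcomp(alt_c) }
  if (substr(cds_seq, idx, idx) != ref_c) return("unknown")
  codon_i <- (idx - 1) %/% 3
  codon <- substr(cds_seq, codon_i * 3 + 1, codon_i * 3 + 3)
  off <- idx - codon_i * 3
  alt_codon <- codon
  substr(alt_codon, off, off) <- alt_c
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(alt_codon)
  if (is.na(aa_ref) || is.na(aa_alt)) return("unknown")
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

#' Read a pseudo-BED regulatory-element file
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open, BED convention),
#' `element_id`, `connected` (comma list of regulated genomic features).
#'
#' @param path input TSV/BED path (with header).
#' @return data.frame with an added `length_bp = end - start` column.
#' @export
read_pseudo_bed <- function(path) {
  b <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "element_id", "connected")
  if (!all(need %in% names(b)))
    stop("pseudo-BED needs columns: ", paste(need, collapse = ", "))
  if (any(b$end <= b$start)) stop("element with non-positive length")
  if (any(!nzchar(b$connected)))
    stop("every element needs >= 1 connected feature")
  b$length_bp <- b$end - b$start
  b
}

#' Convert 1-based inclusive element intervals to pseudo-BED
#'
#' Mirrors the conversion of a GFF-style regulatory-element table (1-based
#' inclusive) into the 0-based half-open pseudo-BED used for intersection.
#'
#' @param elements data.frame with 1-based `start`, `end` columns.
#' @return the table with BED coordinates (`start - 1`, `end`).
#' @export
elements_to_pseudo_bed <- function(elements) {
  elements$start <- elements$start - 1L
  elements$length_bp <- elements$end - elements$start
  elements
}

#' Intersect hit variants with regulatory elements
#'
#' BED-convention intersection: a hit at 1-based position `p` overlaps an
#' element `[s, e)` (0-based half-open) iff `s <= p - 1 < e`.  Produces the
#' two standard summaries: per element (id, n hits, hit list) and per
#' connected genomic feature (feature, supporting elements, union of hits) —
#' an element can regulate several features and a feature can be regulated by
#' several elements.
#'
#' @param hits data.frame with `chrom`, `pos` (1-based) and optionally a `key`
#'   column used in hit lists.
#' @param elements pseudo-BED data.frame ([read_pseudo_bed()]).
#' @return list with `per_element` and `per_feature` data.frames.
#' @export
intersect_regulatory <- function(hits, elements) {
  key <- if ("key" %in% names(hits)) hits$key else paste(hits$chrom, hits$pos)
  if (nrow(hits)) {
    hr <- GenomicRanges::GRanges(hits$chrom, IRanges::IRanges(hits$pos, hits$pos))
    er <- GenomicRanges::GRanges(elements$chrom,
                                 IRanges::IRanges(elements$start + 1L,
                                                  elements$end))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(hr, er))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  } else qh <- sh <- integer(0)
  hit_list <- split(key[qh], elements$element_id[sh])
  per_element <- data.frame(
    element_id = elements$element_id,
    chrom = elements$chrom, start = elements$start, end = elements$end,
    length_bp = elements$length_bp, connected = elements$connected,
    n_hits = as.integer(table(factor(elements$element_id[sh],
                                     levels = elements$element_id))),
    stringsAsFactors = FALSE)
  per_element$hits <- vapply(per_element$element_id, function(id)
    paste(unique(hit_list[[id]]), collapse = ","), "")
  feat_of <- strsplit(elements$connected, ",", fixed = TRUE)
  feats <- sort(unique(unlist(feat_of)))
  per_feature <- do.call(rbind, lapply(feats, function(f) {
    els <- which(vapply(feat_of, function(v) f %in% v, logical(1)))
    hh <- unique(unlist(hit_list[elements$element_id[els]]))
    data.frame(feature = f,
               n_elements = length(els),
               elements = paste(elements$element_id[els], collapse = ","),
               n_hits = length(hh),
               hits = paste(hh, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  list(per_element = per_element, per_feature = per_feature %||%
         data.frame(feature = character(0), n_elements = integer(0),
                    elements = character(0), n_hits = integer(0),
                    hits = character(0)))
}

#' Selection-signal density of regulatory elements
#'
#' @param per_element `per_element` summary from [intersect_regulatory()].
#' @param top_k flag the `top_k` densest elements (default 10, the usual
#'   short-list size).
#' @param keep_zeros keep elements with no hits?
#' @return data.frame sorted by decreasing density (`n_hits` per kb of
#'   element), with a `top` logical column.
#' @export
regulatory_density <- function(per_element, top_k = 10, keep_zeros = FALSE) {
  stopifnot(all(per_element$length_bp > 0))
  out <- per_element
  out$density <- out$n_hits / (out$length_bp / 1000)
  if (!keep_zeros) out <- out[out$n_hits > 0, , drop = FALSE]
  out <- out[order(-out$density, out$element_id), , drop = FALSE]
  out$top <- seq_len(nrow(out)) <= top_k
  rownames(out) <- NULL
  out
}

#' Read a local-ancestry tract file
#'
#' TSV columns: `sample`, `hap` (1/2), `chrom`, `start`, `end` (BED-like
#' 0-based half-open; converted to 1-based inclusive internally), `ancestry`,
#' `posterior`.
#'
#' @param path input path.
#' @return data.frame with 1-based inclusive `start`/`end`.
#' @export
read_tracts <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "hap", "chrom", "start", "end", "ancestry", "posterior")
  if (!all(need %in% names(t)))
    stop("tract file needs columns: ", paste(need, collapse = ", "))
  t$start <- t$start + 1L
  if (any(t$posterior < 0 | t$posterior > 1))
    stop("posteriors must lie in [0, 1]")
  t
}

#' Cross-reference hits with local-ancestry tracts
#'
#' Discards tracts below the posterior threshold, assigns each hit x
#' haplotype the covering tract's ancestry (or `unassigned`), computes the
#' per-hit ancestry proportions over assigned haplotypes only, and summarizes
#' each ancestry as mean +/- sd of those proportions across hits.  Hits
#' covered by no confident tract on any haplotype are excluded from the
#' summary and counted.
#'
#' @param hits data.frame with `chrom`, `pos`.
#' @param tracts tract data.frame with 1-based inclusive intervals
#'   ([read_tracts()] or [make_toy_annotations()]).
#' @param min_posterior confidence threshold, default 0.9.
#' @return list with `per_hit` (hit x ancestry proportion matrix),
#'   `summary` (mean, sd, n per ancestry) and `n_uncovered`.
#' @export
ancestry_crossref <- function(hits, tracts, min_posterior = 0.9) {
  stopifnot(min_posterior >= 0, min_posterior <= 1)
  conf <- tracts[tracts$posterior >= min_posterior, , drop = FALSE]
  labels <- sort(unique(tracts$ancestry))
  prop <- matrix(NA_real_, nrow(hits), length(labels),
                 dimnames = list(NULL, labels))
  n_assigned <- integer(nrow(hits))
  haps <- unique(conf[c("sample", "hap")])
  for (i in seq_len(nrow(hits))) {
    cover <- conf$chrom == hits$chrom[i] & conf$start <= hits$pos[i] &
      conf$end >= hits$pos[i]
    lab <- conf$ancestry[cover]
    n_assigned[i] <- length(lab)
    if (length(lab))
      prop[i, ] <- as.numeric(table(factor(lab, levels = labels))) / length(lab)
  }
  covered <- n_assigned > 0
  summ <- data.frame(
    ancestry = labels,
    mean = colMeans(prop[covered, , drop = FALSE]),
    sd = apply(prop[covered, , drop = FALSE], 2, stats::sd),
    n_hits = sum(covered), row.names = NULL, stringsAsFactors = FALSE)
  list(per_hit = cbind(hits, prop, n_assigned = n_assigned),
       summary = summ, n_uncovered = sum(!covered))
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene`, `exon` and `CDS` features (via \pkg{rtracklayer}) and
#' builds the simplified gene-model table used by the classifiers.  Exons and
#' CDS are grouped by their `Parent`/`gene_id` attribute chain collapsed per
#' gene (isoforms are unioned into one model per gene).
#'
#' @param path GFF3 file.
#' @return gene-model data.frame (see [read_gene_models()]).
#' @export
read_gene_models_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires rtracklayer")
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  ids <- as.character(md$ID)
  parent <- vapply(as.list(md$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "")
  root_of <- function(i) {
    j <- i
    repeat {
      p <- parent[j]
      if (is.na(p)) return(ids[j])
      k <- match(p, ids)
      if (is.na(k)) return(p)
      j <- k
    }
  }
  type <- as.character(md$type)
  genes <- which(type == "gene")
  rows <- lapply(genes, function(gi) {
    gid <- ids[gi]
    name <- if (!is.null(md$Name) && !is.na(md$Name[gi]))
      as.character(md$Name[gi]) else gid
    mine <- vapply(seq_along(gr), function(i) root_of(i) == gid, logical(1))
    ex <- which(mine & type == "exon")
    cd <- which(mine & type == "CDS")
    merge_iv <- function(ix) {
      if (!length(ix)) return(list(s = integer(0), e = integer(0)))
      r <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(gr)[ix],
                                            GenomicRanges::end(gr)[ix]))
      list(s = IRanges::start(r), e = IRanges::end(r))
    }
    exs <- merge_iv(ex); cds <- merge_iv(cd)
    if (!length(exs$s)) {
      exs <- list(s = GenomicRanges::start(gr)[gi], e = GenomicRanges::end(gr)[gi])
    }
    data.frame(gene = name,
               chrom = as.character(GenomicRanges::seqnames(gr)[gi]),
               strand = as.character(GenomicRanges::strand(gr)[gi]),
               tx_start = GenomicRanges::start(gr)[gi],
               tx_end = GenomicRanges::end(gr)[gi],
               exon_starts = paste(exs$s, collapse = ","),
               exon_ends = paste(exs$e, collapse = ","),
               cds_starts = paste(cds$s, collapse = ","),
               cds_ends = paste(cds$e, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  validate_gene_model(out)
  out
}
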