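#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) containing biallelic records with a
#' GT field.  Phase is read from the GT separator: a record is flagged phased
#' when every non-missing call uses `|`.  Multiallelic records, duplicated
#' `(chrom, pos, ref, alt)` keys, and non-diploid calls are hard errors naming
#' the offending record.
#'
#' @param path path to a `.vcf` (optionally gzipped) file.
#' @return a [genotype_matrix()] preserving record order.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    i <- which(grepl(",", alt, fixed = TRUE))[1]
    stop("multiallelic record at ", chrom[i], ":", pos[i],
         "; split or drop multiallelics upstream")
  }
  key <- paste(chrom, pos, ref, alt, sep = ":")
  if (anyDuplicated(key))
    stop("duplicated variant record(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  gt[is.na(gt)] <- "./."
  n <- length(pos)
  gt <- matrix(gt, nrow = n, dimnames = list(NULL, samples))
  phased_call <- matrix(grepl("|", gt, fixed = TRUE), nrow = n)
  # missing calls carry no phase information
  miss <- matrix(gt %in% c(".", "./.", ".|."), nrow = n)
  ok <- miss | matrix(grepl("^[01][/|][01]$", gt), nrow = n)
  if (!all(ok)) {
    i <- which(!ok, arr.ind = TRUE)[1, ]
    stop("malformed or non-diploid GT '", gt[i[1], i[2]], "' at record ",
         chrom[i[1]], ":", pos[i[1]], " sample ", samples[i[2]])
  }
  a1 <- matrix(NA_integer_, n, length(samples))
  a2 <- matrix(NA_integer_, n, length(samples))
  nm <- !miss
  a1[nm] <- as.integer(substr(gt[nm], 1, 1))
  a2[nm] <- as.integer(substr(gt[nm], 3, 3))
  phased <- vapply(seq_len(n), function(i) {
    j <- nm[i, ]
    if (!any(j)) return(FALSE)
    all(phased_call[i, j])
  }, logical(1))
  genotype_matrix(chrom, pos, ref, alt, a1, a2, phased, samples)
}

#' Write a genotype matrix as plain-text VCF v4.2
#'
#' Round-trips with [read_vcf()] on `(chrom, pos, ref, alt, GT)`.  Ancestral
#' states, when known, are written as an `AA=` INFO tag.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  sep <- ifelse(gm$phased, "|", "/")
  g1 <- ifelse(is.na(gm$a1), ".", gm$a1)
  g2 <- ifelse(is.na(gm$a2), ".", gm$a2)
  gt <- matrix(paste0(g1, sep, g2), nrow = n_sites(gm))
  aa <- ifelse(gm$anc_state == "ref", gm$ref,
               ifelse(gm$anc_state == "alt", gm$alt, NA))
  info <- ifelse(is.na(aa), ".", paste0("AA=", aa))
  body <- cbind(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", info, "GT", gt)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"),
    apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ancestral-allele table
#'
#' @param path TSV with header columns `chrom`, `pos`, `ancestral` (one base
#'   per position, A/C/G/T).
#' @return data.frame keyed by `(chrom, pos)`.
#' @export
read_ancestral <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "ancestral") %in% names(a)))
    stop("ancestral table needs columns chrom, pos, ancestral")
  a$ancestral <- toupper(a$ancestral)
  if (!all(a$ancestral %in% c("A", "C", "G", "T")))
    stop("ancestral bases must be A, C, G or T")
  if (anyDuplicated(paste(a$chrom, a$pos)))
    stop("duplicated (chrom, pos) in ancestral table")
  a[c("chrom", "pos", "ancestral")]
}

#' Write an ancestral-allele table
#' @param anc data.frame (`chrom`, `pos`, `ancestral`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ancestral <- function(anc, path) {
  utils::write.table(anc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
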