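#' Genotype matrix container
#'
#' Bundles an individuals x SNPs dosage matrix (0/1/2 counted-allele copies,
#' `NA` for missing calls) with its SNP map (chromosome, physical position,
#' reference and alternate allele). This is the common currency passed between
#' the simulation, QC, relationship-matrix, GWAS and prediction stages.
#'
#' @param dosage numeric matrix, individuals in rows, SNPs in columns; entries
#'   in \{0, 1, 2\} or `NA`. Fractional dosages (mean imputation) are allowed.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`;
#'   one row per column of `dosage`. Positions must be strictly increasing
#'   within a chromosome.
#' @param ids character vector of individual identifiers (defaults to
#'   rownames of `dosage` or `ind_1..ind_n`).
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map, ids = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(ids)) {
    ids <- rownames(dosage)
    if (is.null(ids)) ids <- paste0("ind_", seq_len(nrow(dosage)))
  }
  stopifnot(length(ids) == nrow(dosage))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(required %in% names(map)))
    stop("map must have columns: ", paste(required, collapse = ", "))
  if (nrow(map) != ncol(dosage))
    stop("map rows (", nrow(map), ") != dosage columns (", ncol(dosage), ")")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on chromosome ", ch)
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stop("dosages must lie in [0, 2]")
  rownames(dosage) <- ids
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, map = map, ids = ids), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf("geno_matrix: %d individuals x %d SNPs on %d chromosome(s), %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom)), 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()]
#' @param i individual indices (or logical/character)
#' @param j SNP indices (or logical/character)
#' @param ... unused
#' @return a `geno_matrix` restricted to the selected individuals/SNPs.
#' @export
subset_geno <- function(x, i = NULL, j = NULL, ...) {
  stopifnot(inherits(x, "geno_matrix"))
  if (is.null(i)) i <- seq_len(nrow(x$dosage))
  if (is.null(j)) j <- seq_len(ncol(x$dosage))
  geno_matrix(x$dosage[i, j, drop = FALSE], x$map[j, , drop = FALSE],
              ids = x$ids[i])
}

# ---------------------------------------------------------------------------
# VCF

#' Write genotypes as VCF v4.2
#'
#' Emits a minimal VCF with a GT FORMAT field; missing calls become `./.`.
#' Dosage is the count of the ALT allele, so dosage 0 maps to `0/0`, 1 to
#' `0/1`, 2 to `1/1`. Fractional (imputed) dosages are rounded.
#'
#' @param geno a [geno_matrix()]
#' @param path output file path (plain text, uncompressed)
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- round(geno$dosage)
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=abaloneGS",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$ids), collapse = "\t"))
  body <- data.table::data.table(
    CHROM = geno$map$chrom, POS = geno$map$pos, ID = geno$map$snp_id,
    REF = geno$map$ref, ALT = geno$map$alt, QUAL = ".", FILTER = "PASS",
    INFO = ".", FORMAT = "GT")
  body <- cbind(body, data.table::as.data.table(t(gt)))
  writeLines(header, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Uses `VariantAnnotation::readVcf()` and converts GT calls to ALT-allele
#' dosages. Only biallelic SNPs are retained.
#'
#' @param path VCF file (plain or bgzipped)
#' @return a [geno_matrix()]
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(rr$ALT))
  ref <- as.character(rr$REF)
  keep <- S4Vectors::elementNROWS(rr$ALT) == 1 & nchar(ref) == 1 & nchar(alt) == 1
  gt <- gt[keep, , drop = FALSE]
  dos <- matrix(NA_real_, nrow(gt), ncol(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dos[gt %in% c("1/1", "1|1")] <- 2
  map <- data.frame(
    snp_id = names(rr)[keep],
    chrom  = as.character(GenomicRanges::seqnames(rr))[keep],
    pos    = GenomicRanges::start(rr)[keep],
    ref    = ref[keep], alt = alt[keep],
    stringsAsFactors = FALSE)
  geno_matrix(t(dos), map, ids = colnames(gt))
}

# ---------------------------------------------------------------------------
# PLINK .bed/.bim/.fam (SNP-major). No pre-installed R reader exists for this
# 2-bit codec, so it is implemented here. Codes per PLINK spec: 00=hom A1,
# 01=missing, 10=het, 11=hom A2. A1 is the ALT (counted) allele so that
# dosage round-trips.

#' Write genotypes in PLINK .bed/.bim/.fam format
#'
#' SNP-major `.bed` dialect (magic bytes `6c 1b 01`). The counted (ALT) allele
#' is written as allele 1 in the `.bim`.
#'
#' @param geno a [geno_matrix()]
#' @param prefix output path prefix; `<prefix>.bed/.bim/.fam` are written
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- round(geno$dosage)
  n <- nrow(d); m <- ncol(d)
  # .fam: FID IID father mother sex phenotype
  fam <- data.frame(geno$ids, geno$ids, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(geno$map$chrom, geno$map$snp_id, 0, geno$map$pos,
                    geno$map$alt, geno$map$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  # 2-bit codes indexed by dosage + 1 (NA -> 01b = 1)
  code <- matrix(1L, n, m)                       # missing
  code[!is.na(d) & d == 0] <- 0L                 # hom other allele (A1 count 0 -> 00? see below)
  code[!is.na(d) & d == 1] <- 2L                 # het
  code[!is.na(d) & d == 2] <- 3L                 # hom counted allele
  # PLINK: 00 = hom A1, 11 = hom A2. We store A1 = counted allele, so
  # dosage 2 (two counted copies) must be 00 and dosage 0 must be 11.
  tmp <- code
  code[tmp == 0L] <- 3L
  code[tmp == 3L] <- 0L
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bytes_per_snp - n
  for (j in seq_len(m)) {
    cj <- c(code[, j], rep(0L, pad))
    quad <- matrix(cj, nrow = 4)
    byte <- quad[1, ] + quad[2, ] * 4L + quad[3, ] * 16L + quad[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read PLINK .bed/.bim/.fam genotypes
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` triplet
#' @return a [geno_matrix()] with dosage = copies of the `.bim` allele-1.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + bytes_per_snp * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file")
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit fields, little-endian within byte
  q1 <- body %% 4L
  q2 <- (body %/% 4L) %% 4L
  q3 <- (body %/% 16L) %% 4L
  q4 <- body %/% 64L
  codes <- matrix(rbind(q1, q2, q3, q4), nrow = 4 * bytes_per_snp)
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_real_, n, m)
  dos[codes == 0L] <- 2  # hom A1 (counted allele)
  dos[codes == 2L] <- 1
  dos[codes == 3L] <- 0
  map <- data.frame(snp_id = bim[[2]], chrom = as.character(bim[[1]]),
                    pos = bim[[4]], ref = bim[[6]], alt = bim[[5]],
                    stringsAsFactors = FALSE)
  geno_matrix(dos, map, ids = fam[[2]])
}

# ---------------------------------------------------------------------------
# Small tabular writers used across the pipeline

#' Write phenotypes as CSV
#' @param pheno a phenotype data.frame (see [simulate_phenotype()])
#' @param path output CSV path
#' @export
write_phenotype_csv <- function(pheno, path) {
  data.table::fwrite(pheno, path)
  invisible(path)
}

#' Write a GRM as square CSV (ids in the first column)
#' @param grm a [grm_vanraden()] result
#' @param path output CSV path
#' @export
write_grm_csv <- function(grm, path) {
  m <- as.data.frame(grm$matrix)
  data.table::fwrite(cbind(id = rownames(grm$matrix), m), path)
  invisible(path)
}

#' Write a GRM as a GCTA-style text triplet
#'
#' Emits `<prefix>.grm.id` (one id per line) and `<prefix>.grm` with
#' lower-triangle rows `i j n_snps value`.
#'
#' @param grm a [grm_vanraden()] result
#' @param prefix output path prefix
#' @export
write_grm_gcta <- function(grm, prefix) {
  ids <- rownames(grm$matrix)
  writeLines(paste(ids, ids, sep = "\t"), paste0(prefix, ".grm.id"))
  n <- nrow(grm$matrix)
  idx <- which(lower.tri(grm$matrix, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(i = idx[, 1], j = idx[, 2],
                    n = grm$n_snps, value = grm$matrix[idx])
  data.table::fwrite(out, paste0(prefix, ".grm"), sep = "\t", col.names = FALSE)
  invisible(prefix)
}

#' Write a toy GFF3 gene annotation
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `gene_id`
#'   (1-based inclusive coordinates) and optionally `strand`.
#' @param path output GFF3 path
#' @export
write_gff3 <- function(genes, path) {
  strand <- if ("strand" %in% names(genes)) genes$strand else "+"
  lines <- sprintf("%s\tabaloneGS\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                   genes$chrom, as.integer(genes$start), as.integer(genes$end),
                   strand, genes$gene_id, genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
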