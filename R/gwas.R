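# Mixed-linear-model association scan (EMMAX-style): variance components are
# estimated once under the null model, the data are rotated by the GRM
# eigenvectors, and each marker is tested by a Wald test in the resulting
# weighted least-squares problem. O(n) per marker after the one-off O(n^3)
# decomposition.

#' Fit the null mixed model for association scanning
#'
#' REML fit of `y = X b + g + e`, `g ~ N(0, G sigma_g2)`, with the fixed
#' covariates only (intercept, batch, leading PCs). Returns the variance
#' components and the spectral cache reused by [scan_association()].
#'
#' @param y phenotype vector
#' @param covariates fixed-effect design matrix (an intercept column is added
#'   if absent)
#' @param grm a [grm_vanraden()] result
#' @param ridge diagonal ridge for invertibility (default 1e-6)
#' @param fix_lambda optional fixed variance ratio (see [gblup_reml()]);
#'   `fix_lambda = 0` makes the downstream scan identical to OLS
#' @return object of class `mlm_null` wrapping the [gblup_reml()] fit.
#' @export
fit_null_mlm <- function(y, covariates = NULL, grm, ridge = 1e-6,
                         fix_lambda = NULL) {
  n <- length(y)
  X <- if (is.null(covariates)) matrix(1, n, 1) else as.matrix(covariates)
  if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0)))
    X <- cbind(intercept = 1, X)
  fit <- gblup_reml(y, X, grm, ridge = ridge, fix_lambda = fix_lambda)
  structure(list(fit = fit, y = y, X = X,
                 sigma_g2 = fit$varcomp$sigma_g2,
                 sigma_e2 = fit$varcomp$sigma_e2,
                 h2 = fit$varcomp$h2), class = "mlm_null")
}

#' @export
print.mlm_null <- function(x, ...) {
  cat(sprintf("mlm_null: sigma_g2=%.4f sigma_e2=%.4f h2=%.3f\n",
              x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

#' Single-marker mixed-model association scan
#'
#' Per SNP, a Wald test of the additive effect in the rotated model with
#' variance components fixed at the null fit (the EMMAX approximation).
#' Effects are reported per copy of the minor allele; p-values are two-sided
#' and invariant to allele relabeling. Monomorphic SNPs get `beta = 0`,
#' `p = 1` and a flag.
#'
#' @param genotypes a complete [geno_matrix()]
#' @param y phenotype vector (same order of individuals)
#' @param covariates fixed-effect design passed to the null model (ignored if
#'   `null_fit` given)
#' @param null_fit a [fit_null_mlm()] object fitted on the same individuals
#' @param var_p phenotypic variance used for PVE (default `var(y)`)
#' @return an `assoc_result` data.frame: snp_id, chrom, pos, minor/major
#'   allele, maf, beta, se, p_value, pve, monomorphic flag.
#' @export
scan_association <- function(genotypes, y, covariates = NULL,
                             null_fit = NULL, var_p = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosage
  if (anyNA(d)) stop("scan requires complete genotypes; impute first")
  n <- nrow(d)
  stopifnot(length(y) == n)
  if (is.null(null_fit)) {
    grm <- grm_vanraden(genotypes)
    null_fit <- fit_null_mlm(y, covariates, grm)
  }
  stopifnot(inherits(null_fit, "mlm_null"))
  fit <- null_fit$fit
  U <- fit$eigen$U; dd <- fit$eigen$d
  lambda <- fit$lambda
  w <- 1 / (lambda * dd + 1)
  sw <- sqrt(w)

  ys <- crossprod(U, y) * sw
  Xs <- crossprod(U, null_fit$X) * as.vector(sw)
  Gs <- crossprod(U, d) * as.vector(sw)

  # FWL: residualize phenotype and markers against the covariates
  qx <- qr(Xs)
  ey <- qr.resid(qx, ys)
  EG <- qr.resid(qx, Gs)

  gtg <- colSums(EG^2)
  gty <- as.vector(crossprod(EG, ey))
  p_cov <- qx$rank
  df <- n - p_cov - 1

  maf <- compute_maf(d)
  freq <- attr(maf, "freq")
  mono <- gtg < n * 1e-12 | maf == 0
  beta_raw <- ifelse(mono, 0, gty / gtg)
  rss <- sum(ey^2) - beta_raw^2 * gtg
  rss <- pmax(rss, 0)
  se <- ifelse(mono, NA_real_, sqrt(rss / df / gtg))
  tval <- ifelse(mono, 0, beta_raw / se)
  pval <- ifelse(mono, 1, 2 * stats::pt(abs(tval), df, lower.tail = FALSE))

  # report effect per minor-allele copy: flip sign where counted allele major
  flip <- freq > 0.5
  beta <- ifelse(flip, -beta_raw, beta_raw)
  minor <- ifelse(flip, genotypes$map$ref, genotypes$map$alt)
  major <- ifelse(flip, genotypes$map$alt, genotypes$map$ref)

  if (is.null(var_p)) var_p <- stats::var(y)
  pve <- compute_pve(beta, as.vector(maf), var_p)

  res <- data.frame(
    snp_id = genotypes$map$snp_id, chrom = genotypes$map$chrom,
    pos = genotypes$map$pos, minor_allele = minor, major_allele = major,
    maf = as.vector(maf), beta = beta, se = se, p_value = pval, pve = pve,
    monomorphic = mono, stringsAsFactors = FALSE)
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Genome-wide and suggestive significance thresholds
#'
#' Bonferroni genome-wide threshold `alpha / m_tests` plus the conventional
#' suggestive threshold. `-log10` values are carried to 2 decimals for
#' reporting.
#'
#' @param m_tests number of tests (SNPs)
#' @param alpha family-wise error level (default 0.05)
#' @param suggestive suggestive p-value threshold (default 1e-5)
#' @return object of class `sig_thresholds`: `genome_wide_p`, `suggestive_p`,
#'   `m_tests`, `alpha`, `neglog10` (both, rounded to 2 dp).
#' @export
compute_thresholds <- function(m_tests, alpha = 0.05, suggestive = 1e-5) {
  if (m_tests < 1) stop("m_tests must be >= 1")
  gw <- alpha / m_tests
  structure(list(genome_wide_p = gw, suggestive_p = max(gw, suggestive),
                 m_tests = m_tests, alpha = alpha,
                 neglog10 = c(genome_wide = round(-log10(gw), 2),
                              suggestive = round(-log10(max(gw, suggestive)), 2))),
            class = "sig_thresholds")
}

#' @export
print.sig_thresholds <- function(x, ...) {
  cat(sprintf("thresholds: genome-wide p <= %.3g (-log10 = %.2f); suggestive p <= %.3g (-log10 = %.2f); m = %d\n",
              x$genome_wide_p, x$neglog10["genome_wide"],
              x$suggestive_p, x$neglog10["suggestive"], x$m_tests))
  invisible(x)
}

#' Classify SNPs by significance
#'
#' Boundary convention: a p-value exactly equal to a threshold passes it
#' (genome-wide if `p <= genome_wide_p`; suggestive if
#' `genome_wide_p < p <= suggestive_p`).
#'
#' @param results an `assoc_result` (or any data.frame with `p_value`)
#' @param thresholds a [compute_thresholds()] object
#' @return list: `table` (results plus a `class` column) and `counts`
#'   (named vector: genome_wide, suggestive, none)
#' @export
classify_snps <- function(results, thresholds) {
  stopifnot(inherits(thresholds, "sig_thresholds"))
  p <- results$p_value
  cls <- ifelse(p <= thresholds$genome_wide_p, "genome-wide",
                ifelse(p <= thresholds$suggestive_p, "suggestive", "none"))
  results$class <- cls
  counts <- c(genome_wide = sum(cls == "genome-wide"),
              suggestive = sum(cls == "suggestive"),
              none = sum(cls == "none"))
  list(table = results, counts = counts)
}

#' Per-SNP phenotypic variance explained
#'
#' `PVE = 100 * 2 p (1 - p) beta^2 / var_p` (percent), the standard
#' single-marker decomposition under Hardy-Weinberg.
#'
#' @param beta additive effect per minor-allele copy
#' @param maf minor allele frequency
#' @param var_p phenotypic variance (> 0)
#' @return PVE in percent
#' @export
compute_pve <- function(beta, maf, var_p) {
  if (any(var_p <= 0)) stop("var_p must be > 0")
  100 * 2 * maf * (1 - maf) * beta^2 / var_p
}

#' Annotate significant SNPs with nearby genes
#'
#' For each SNP at or below the suggestive threshold, reports every gene
#' overlapping it or whose boundary lies within `window_bp`; when none
#' qualifies, the nearest gene is reported with its distance and a
#' "none within window" flag. SNPs inside a gene span are labeled "genic"
#' (the toy annotation carries no exon structure), otherwise "intergenic".
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos` (typically the
#'   significant rows of a classified `assoc_result`)
#' @param annotation path to a GFF3 file or a `GRanges` of gene features
#'   (metadata column `ID` or `Name` used as the gene id)
#' @param window_bp search window around each SNP (default 50000)
#' @return data.frame: snp_id, chrom, pos, gene_id, distance_bp, region,
#'   within_window
#' @export
annotate_candidates <- function(snps, annotation, window_bp = 50000) {
  genes <- if (is.character(annotation)) {
    gr <- rtracklayer::import(annotation, format = "gff3")
    gr[gr$type == "gene"]
  } else annotation
  gene_id <- if (!is.null(genes$ID)) genes$ID else
    if (!is.null(genes$Name)) genes$Name else
      paste0("gene_", seq_along(genes))
  unmatched <- setdiff(unique(snps$chrom),
                       as.character(GenomicRanges::seqnames(genes)))
  covered_chr <- as.character(GenomicRanges::seqnames(genes))
  out <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    ch <- as.character(snps$chrom[i]); pos <- snps$pos[i]
    on_chr <- which(covered_chr == ch)
    if (length(on_chr) == 0) {
      out[[i]] <- data.frame(snp_id = snps$snp_id[i], chrom = ch, pos = pos,
                             gene_id = NA_character_, distance_bp = NA_real_,
                             region = "intergenic", within_window = FALSE,
                             stringsAsFactors = FALSE)
      next
    }
    gs <- GenomicRanges::start(genes)[on_chr]
    ge <- GenomicRanges::end(genes)[on_chr]
    dist <- ifelse(pos < gs, gs - pos, ifelse(pos > ge, pos - ge, 0))
    inside <- dist == 0
    region <- if (any(inside)) "genic" else "intergenic"
    hit <- which(dist <= window_bp)
    if (length(hit) == 0) hit <- which.min(dist)
    out[[i]] <- data.frame(snp_id = snps$snp_id[i], chrom = ch, pos = pos,
                           gene_id = gene_id[on_chr][hit],
                           distance_bp = dist[hit], region = region,
                           within_window = dist[hit] <= window_bp,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "unmatched_chromosomes") <- unmatched
  res
}

#' Published association results for heat-stress attachment duration
#'
#' The 13 SNPs reported as associated with the abalone heat-tolerance
#' phenotype (chromosome, position, region label, minor/major allele, MAF,
#' p-value and printed PVE in percent). Shipped as a plain-text worked-example
#' input for the significance-classification and PVE arithmetic checks; the
#' underlying genotypes are not public, so these rows are inputs, not
#' outputs, of this package.
#'
#' @return data.frame with one row per reported SNP
#' @export
reported_gwas_snps <- function() {
  path <- system.file("extdata", "reported_gwas_snps.tsv",
                      package = "abaloneGS")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Plot-ready Manhattan and QQ tables
#'
#' Manhattan x-coordinate = cumulative chromosome offset + position (raw
#' position for a single chromosome). QQ expected quantiles use
#' `-log10((rank - 0.5) / m)`.
#'
#' @param results an `assoc_result`
#' @return list: `manhattan` (snp_id, chrom, pos, x, neglog10_p) and `qq`
#'   (expected, observed, both `-log10`).
#' @export
export_manhattan_qq <- function(results) {
  chr <- unique(results$chrom)
  offsets <- stats::setNames(numeric(length(chr)), chr)
  run <- 0
  for (cc in chr) {
    offsets[cc] <- run
    run <- run + max(results$pos[results$chrom == cc])
  }
  man <- data.frame(snp_id = results$snp_id, chrom = results$chrom,
                    pos = results$pos,
                    x = offsets[as.character(results$chrom)] + results$pos,
                    neglog10_p = -log10(results$p_value),
                    stringsAsFactors = FALSE)
  m <- nrow(results)
  obs <- sort(-log10(results$p_value), decreasing = TRUE)
  expd <- -log10((seq_len(m) - 0.5) / m)
  list(manhattan = man, qq = data.frame(expected = expd, observed = obs))
}
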