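#' QC thresholds
#'
#' Defaults follow the standard array-QC criteria used for the abalone panel:
#' MAF > 0.05, SNP call rate > 0.95, individual call rate > 0.80. All filters
#' use strict inequalities (a SNP at MAF exactly 0.05 is removed).
#'
#' @param maf_min minimum minor allele frequency (exclusive)
#' @param snp_call_min minimum SNP call rate (exclusive)
#' @param ind_call_min minimum individual call rate (exclusive)
#' @return a `qc_thresholds` object.
#' @export
qc_thresholds <- function(maf_min = 0.05, snp_call_min = 0.95,
                          ind_call_min = 0.80) {
  for (v in c(maf_min, snp_call_min, ind_call_min))
    if (v < 0 || v > 1) stop("thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, snp_call_min = snp_call_min,
                 ind_call_min = ind_call_min), class = "qc_thresholds")
}

#' Per-SNP minor allele frequency
#'
#' `MAF = min(p, 1 - p)` with `p = sum(dosage) / (2 * n_called)`, computed
#' over non-missing calls. SNPs with no calls at all get `NA` (undefined
#' sentinel) and are flagged via the `all_missing` attribute.
#'
#' @param genotypes a [geno_matrix()] or plain dosage matrix
#' @return numeric vector of MAF in \[0, 0.5\] (NA where undefined)
#' @export
compute_maf <- function(genotypes) {
  d <- if (inherits(genotypes, "geno_matrix")) genotypes$dosage else genotypes
  called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * called)
  maf <- pmin(p, 1 - p)
  maf[called == 0] <- NA_real_
  attr(maf, "all_missing") <- unname(which(called == 0))
  attr(maf, "freq") <- p
  maf
}

#' Apply genotype quality control
#'
#' Filter order is fixed and documented: (1) drop individuals with call rate
#' <= `ind_call_min`; (2) drop SNPs with call rate <= `snp_call_min`;
#' (3) drop SNPs with MAF <= `maf_min`, with MAF recomputed after steps 1-2.
#' Running the filter twice is a no-op (idempotence).
#'
#' @param genotypes a [geno_matrix()]
#' @param thresholds a [qc_thresholds()]
#' @return list: `genotypes` (filtered `geno_matrix`) and `report`
#'   (a `qc_report` with per-filter removal counts).
#' @export
apply_qc <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "geno_matrix"),
            inherits(thresholds, "qc_thresholds"))
  d <- genotypes$dosage
  if (length(d) == 0) stop("empty genotype matrix")
  n_in <- nrow(d); m_in <- ncol(d)

  ind_call <- rowMeans(!is.na(d))
  keep_ind <- ind_call > thresholds$ind_call_min
  n_ind_removed <- sum(!keep_ind)
  if (!any(keep_ind)) {
    rep <- qc_report(n_in, m_in, 0, 0, n_ind_removed, m_in, 0, NA)
    stop(structure(class = c("qc_all_removed", "error", "condition"),
                   list(message = "QC removed all individuals",
                        call = sys.call(), report = rep)))
  }
  d2 <- d[keep_ind, , drop = FALSE]

  snp_call <- colMeans(!is.na(d2))
  keep_call <- snp_call > thresholds$snp_call_min
  n_snp_call_removed <- sum(!keep_call)
  d3 <- d2[, keep_call, drop = FALSE]

  maf <- compute_maf(d3)
  keep_maf <- !is.na(maf) & maf > thresholds$maf_min
  n_snp_maf_removed <- sum(!keep_maf)

  keep_snp <- which(keep_call)[keep_maf]
  if (length(keep_snp) == 0) {
    rep <- qc_report(n_in, m_in, sum(keep_ind), 0, n_ind_removed,
                     n_snp_call_removed, n_snp_maf_removed, NA)
    stop(structure(class = c("qc_all_removed", "error", "condition"),
                   list(message = "QC removed all SNPs",
                        call = sys.call(), report = rep)))
  }
  out <- subset_geno(genotypes, i = which(keep_ind), j = keep_snp)
  report <- qc_report(n_in, m_in, nrow(out$dosage), ncol(out$dosage),
                      n_ind_removed, n_snp_call_removed, n_snp_maf_removed,
                      mean(is.na(out$dosage)))
  list(genotypes = out, report = report)
}

qc_report <- function(n_ind_in, n_snps_in, n_ind_out, n_snps_out,
                      removed_ind_call, removed_snp_call, removed_snp_maf,
                      mean_missing_after) {
  structure(list(
    n_ind_in = n_ind_in, n_snps_in = n_snps_in,
    n_ind_out = n_ind_out, n_snps_out = n_snps_out,
    removed = list(individual_call_rate = removed_ind_call,
                   snp_call_rate = removed_snp_call,
                   snp_maf = removed_snp_maf),
    mean_missing_after = mean_missing_after), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d -> %d individuals, %d -> %d SNPs\n",
              x$n_ind_in, x$n_ind_out, x$n_snps_in, x$n_snps_out))
  cat(sprintf("  removed: %d individuals (call rate), %d SNPs (call rate), %d SNPs (MAF)\n",
              x$removed$individual_call_rate, x$removed$snp_call_rate,
              x$removed$snp_maf))
  cat(sprintf("  mean missing rate after filtering: %.4f\n",
              x$mean_missing_after))
  invisible(x)
}

#' Serialize a QC report as JSON
#' @param report a `qc_report`
#' @param path optional output path; if `NULL` the JSON string is returned
#' @export
qc_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(path)) }
  js
}

#' Naive single-marker imputation
#'
#' Fills missing calls per SNP either with the mean dosage `2p` (continuous;
#' preserves the allele frequency exactly) or with a draw from the
#' Hardy-Weinberg genotype distribution at the observed frequency `p`.
#' Adequate at the ~0.8% missing rates this pipeline assumes; haplotype-aware
#' imputation is out of scope.
#'
#' @param genotypes a [geno_matrix()] (post QC)
#' @param mode `"mean"` or `"sample"`
#' @param seed integer RNG seed (sample mode)
#' @return a complete `geno_matrix` (no missing values)
#' @export
impute_naive <- function(genotypes, mode = c("mean", "sample"), seed = 1L) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  mode <- match.arg(mode)
  d <- genotypes$dosage
  if (!anyNA(d)) return(genotypes)
  maf <- compute_maf(d)
  p <- attr(maf, "freq")
  if (anyNA(maf)) stop("cannot impute all-missing SNPs; run QC first")
  if (mode == "mean") {
    for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- 2 * p[j]
  } else {
    set.seed(seed)
    for (j in which(colSums(is.na(d)) > 0)) {
      miss <- which(is.na(d[, j]))
      d[miss, j] <- sample(0:2, length(miss), replace = TRUE,
                           prob = c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2))
    }
  }
  geno_matrix(d, genotypes$map, ids = genotypes$ids)
}
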