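#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = Z Z' / (2 * sum_j p_j (1 - p_j))` with `Z = M - 2P` the
#' column-centered dosage matrix. Frequencies `p_j` are estimated from the
#' sample unless supplied. Monomorphic-only input has a zero denominator and
#' is an error; individual monomorphic SNPs contribute nothing and are kept.
#'
#' @param genotypes a complete [geno_matrix()] (no missing dosages) or a plain
#'   dosage matrix
#' @param allele_freqs optional per-SNP counted-allele frequencies to use in
#'   place of the in-sample estimates
#' @param ridge value added to the diagonal (default 0; downstream mixed-model
#'   fitters apply their own small ridge for invertibility)
#' @return an object of class `grm`: `matrix` (n x n, symmetric),
#'   `denominator`, `allele_freqs`, `n_snps`.
#' @export
grm_vanraden <- function(genotypes, allele_freqs = NULL, ridge = 0) {
  d <- if (inherits(genotypes, "geno_matrix")) genotypes$dosage else as.matrix(genotypes)
  if (anyNA(d)) stop("GRM requires complete genotypes; impute first")
  if (ncol(d) < 2) stop("need at least 2 SNPs")
  p <- if (is.null(allele_freqs)) colMeans(d) / 2 else allele_freqs
  if (length(p) != ncol(d)) stop("allele_freqs length mismatch")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("zero denominator: all SNPs monomorphic")
  Z <- sweep(d, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  if (ridge > 0) diag(G) <- diag(G) + ridge
  ids <- if (inherits(genotypes, "geno_matrix")) genotypes$ids else rownames(d)
  if (!is.null(ids)) dimnames(G) <- list(ids, ids)
  structure(list(matrix = G, denominator = denom, allele_freqs = p,
                 n_snps = ncol(d), ridge = ridge), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d, %d SNPs, mean diagonal %.4f\n",
              nrow(x$matrix), ncol(x$matrix), x$n_snps, mean(diag(x$matrix))))
  invisible(x)
}

# Tracy-Widom (GOE, beta = 1) upper-tail quantiles. Standard published
# significance points; p-values between grid points are log-linearly
# interpolated, clamped to the grid ends.
tw1_table <- data.frame(
  stat = c(-3.90, -3.18, -2.78, -2.41, -1.91, -1.27, -0.59,  0.45,  0.98,
            1.45,  2.02,  2.42,  3.27),
  p    = c(0.999, 0.99, 0.975, 0.95, 0.90, 0.75, 0.50, 0.10, 0.05,
           0.025, 0.01, 0.005, 0.001))

tw1_pvalue <- function(x) {
  tab <- tw1_table
  sapply(x, function(xi) {
    if (is.na(xi)) return(NA_real_)
    if (xi <= tab$stat[1]) return(tab$p[1])
    if (xi >= tab$stat[nrow(tab)]) return(tab$p[nrow(tab)])
    i <- findInterval(xi, tab$stat)
    x0 <- tab$stat[i]; x1 <- tab$stat[i + 1]
    lp0 <- log(tab$p[i]); lp1 <- log(tab$p[i + 1])
    exp(lp0 + (lp1 - lp0) * (xi - x0) / (x1 - x0))
  })
}

#' Principal-component population structure with Tracy-Widom tests
#'
#' Eigendecomposition of the genomic relationship matrix; component scores are
#' eigenvectors scaled by the square root of their eigenvalue. Each leading
#' eigenvalue is tested against the Tracy-Widom (GOE) null using the
#' moment-matching estimate of the effective marker number from the spread of
#' the remaining eigenvalues; significance is declared at `alpha`.
#'
#' @param grm a [grm_vanraden()] result
#' @param k number of components to return (truncated to rank with a warning)
#' @param alpha per-component significance level (default 0.05)
#' @return an object of class `structure_result`: `scores` (n x k),
#'   `eigenvalues` (descending, all returned), `tracy_widom` (data.frame with
#'   statistic, p-value, significant flag per component), `n_significant`.
#' @export
pca_structure <- function(grm, k = 10, alpha = 0.05) {
  stopifnot(inherits(grm, "grm"))
  if (k < 1) stop("k must be >= 1")
  G <- grm$matrix
  n <- nrow(G)
  e <- eigen(G, symmetric = TRUE)
  vals <- e$values
  # centered GRM has rank <= n-1; treat tiny/negative eigenvalues as null
  pos <- which(vals > max(vals) * 1e-9)
  rank <- length(pos)
  if (k > rank) {
    warning("k = ", k, " exceeds rank ", rank, "; truncating")
    k <- rank
  }
  scores <- sweep(e$vectors[, seq_len(k), drop = FALSE], 2,
                  sqrt(pmax(vals[seq_len(k)], 0)), "*")
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))

  tw <- data.frame(component = seq_len(k), statistic = NA_real_,
                   p_value = NA_real_, significant = FALSE)
  lam <- vals[pos]
  for (i in seq_len(k)) {
    rem <- lam[i:length(lam)]
    L <- length(rem)
    if (L < 3) break
    S1 <- sum(rem); S2 <- sum(rem^2)
    # Patterson moment estimator of the effective number of markers
    n_hat <- ((L + 1) * S1^2) / ((L - 1) * S2 - S1^2)
    if (!is.finite(n_hat) || n_hat <= 1) next
    l1 <- L * rem[1] / S1
    mu <- (sqrt(n_hat - 1) + sqrt(L))^2 / n_hat
    sig <- (sqrt(n_hat - 1) + sqrt(L)) / n_hat *
      (1 / sqrt(n_hat - 1) + 1 / sqrt(L))^(1 / 3)
    tw$statistic[i] <- (l1 - mu) / sig
    tw$p_value[i] <- tw1_pvalue(tw$statistic[i])
    tw$significant[i] <- !is.na(tw$p_value[i]) && tw$p_value[i] < alpha
  }
  structure(list(scores = scores, eigenvalues = vals, tracy_widom = tw,
                 n_significant = sum(tw$significant), k = k, alpha = alpha),
            class = "structure_result")
}

#' @export
print.structure_result <- function(x, ...) {
  cat(sprintf("structure_result: %d PCs, %d significant (Tracy-Widom, alpha=%.2f)\n",
              x$k, x$n_significant, x$alpha))
  print(utils::head(x$tracy_widom, x$k), row.names = FALSE)
  invisible(x)
}

#' Add a diagonal ridge to a GRM
#'
#' Guarantees positive definiteness for downstream mixed-model equations.
#'
#' @param grm a [grm_vanraden()] result
#' @param ridge value added to the diagonal (default 1e-6)
#' @return the ridged `grm`
#' @export
grm_ridge <- function(grm, ridge = 1e-6) {
  stopifnot(inherits(grm, "grm"))
  diag(grm$matrix) <- diag(grm$matrix) + ridge
  grm$ridge <- grm$ridge + ridge
  grm
}
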