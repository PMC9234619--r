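#' Simulate a founder haplotype pool
#'
#' Generates `2 * n_founders` haplotypes at `m` biallelic SNPs spread over the
#' supplied chromosomes. Per-SNP founder allele frequencies are drawn uniformly
#' from `maf_range`. Within-chromosome linkage disequilibrium follows a
#' first-order autoregressive (haplotype-copying style) process: each
#' haplotype's allele indicators are thresholded from a latent standard-normal
#' AR(1) chain with correlation `ld_rho`, so marginal frequencies are exact and
#' `ld_rho = 0` gives fully independent sites.
#'
#' @param n_founders number of founder individuals (>= 2)
#' @param m total number of SNPs (>= 1), apportioned to chromosomes
#'   proportionally to their length
#' @param chrom_lengths named or unnamed numeric vector of chromosome lengths
#'   in bp (one entry per chromosome)
#' @param maf_range length-2 interval within (0, 0.5] for founder frequencies
#' @param ld_rho latent AR(1) correlation in \[0, 1) controlling LD decay
#' @param seed integer RNG seed (full determinism contract)
#' @return an object of class `founder_pool`: `haplotypes` (2n x m binary
#'   matrix), `snp_map`, `allele_freqs`.
#' @export
simulate_founders <- function(n_founders, m, chrom_lengths,
                              maf_range = c(0.05, 0.5), ld_rho = 0.9,
                              seed = 1L) {
  if (n_founders < 2) stop("need at least 2 founders")
  if (m < 1) stop("need at least 1 SNP")
  if (length(chrom_lengths) == 0) stop("empty chromosome list")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be an interval within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  set.seed(seed)

  n_chr <- length(chrom_lengths)
  chr_names <- names(chrom_lengths)
  if (is.null(chr_names)) chr_names <- paste0("chr", seq_len(n_chr))
  # apportion SNPs by length, at least one per chromosome where possible
  frac <- chrom_lengths / sum(chrom_lengths)
  counts <- floor(frac * m)
  rem <- m - sum(counts)
  if (rem > 0) {
    extra <- order(frac * m - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  chrom <- rep(chr_names, counts)
  pos <- unlist(lapply(seq_len(n_chr), function(c) {
    if (counts[c] == 0) return(integer(0))
    sort(sample.int(chrom_lengths[c], counts[c]))
  }), use.names = FALSE)

  p <- stats::runif(m, maf_range[1], maf_range[2])
  H <- 2L * n_founders
  # latent AR(1) per haplotype, restarted at chromosome boundaries
  Z <- matrix(stats::rnorm(H * m), H, m)
  if (ld_rho > 0 && m > 1) {
    new_chr <- c(TRUE, chrom[-1] != chrom[-m])
    s <- sqrt(1 - ld_rho^2)
    for (j in 2:m) {
      if (!new_chr[j]) Z[, j] <- ld_rho * Z[, j - 1] + s * Z[, j]
    }
  }
  hap <- matrix(0L, H, m)
  thr <- stats::qnorm(p)
  hap[sweep(Z, 2, thr, "<")] <- 1L
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
  snp_map <- data.frame(
    snp_id = paste0("snp_", seq_len(m)), chrom = chrom, pos = pos,
    ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  structure(list(haplotypes = hap, snp_map = snp_map, allele_freqs = p,
                 n_founders = n_founders, seed = seed),
            class = "founder_pool")
}

#' @export
print.founder_pool <- function(x, ...) {
  cat(sprintf("founder_pool: %d founders, %d SNPs on %d chromosome(s)\n",
              x$n_founders, ncol(x$haplotypes),
              length(unique(x$snp_map$chrom))))
  invisible(x)
}

#' Random-mate founders into an offspring population
#'
#' Each offspring is formed from two distinct founders drawn at random; each
#' parent contributes one gamete produced with exactly one crossover per
#' chromosome at a uniform position (simplest model consistent with linkage),
#' starting from a randomly chosen parental haplotype. Full-sib and half-sib
#' families arise naturally from the random draws.
#'
#' @param pool a [simulate_founders()] pool
#' @param n_offspring number of offspring to generate
#' @param seed integer RNG seed
#' @return list with `genotypes` (a [geno_matrix()]) and `pedigree`
#'   (data.frame: offspring id, sire, dam as 0-based founder indices).
#' @export
random_mate <- function(pool, n_offspring, seed = 1L) {
  stopifnot(inherits(pool, "founder_pool"))
  if (pool$n_founders < 2) stop("need at least 2 founders to mate")
  set.seed(seed)
  m <- ncol(pool$haplotypes)
  chrom <- pool$snp_map$chrom
  chr_levels <- unique(chrom)
  chr_idx <- lapply(chr_levels, function(cc) which(chrom == cc))

  gamete <- function(parent) {
    h1 <- pool$haplotypes[2L * parent - 1L, ]
    h2 <- pool$haplotypes[2L * parent, ]
    g <- integer(m)
    for (ii in chr_idx) {
      L <- length(ii)
      cut <- sample.int(L, 1)                 # crossover after this site
      first <- sample(c(TRUE, FALSE), 1)
      take1 <- if (first) seq_len(L) <= cut else seq_len(L) > cut
      g[ii] <- ifelse(take1, h1[ii], h2[ii])
    }
    g
  }

  dosage <- matrix(0L, n_offspring, m)
  sire <- integer(n_offspring); dam <- integer(n_offspring)
  for (i in seq_len(n_offspring)) {
    par <- sample.int(pool$n_founders, 2, replace = FALSE)
    sire[i] <- par[1]; dam[i] <- par[2]
    dosage[i, ] <- gamete(par[1]) + gamete(par[2])
  }
  geno <- geno_matrix(dosage, pool$snp_map,
                      ids = paste0("ind_", seq_len(n_offspring)))
  pedigree <- data.frame(id = geno$ids, sire = sire - 1L, dam = dam - 1L,
                         stringsAsFactors = FALSE)
  list(genotypes = geno, pedigree = pedigree, seed = seed)
}

#' Define a sparse additive trait architecture
#'
#' Samples QTL positions and additive effects for a polygenic trait of many
#' minor-effect loci. Effects are drawn from a double-exponential (Laplace)
#' distribution by default, so a few loci reach the ~1% phenotypic-variance
#' scale seen in sparse architectures, then rescaled on the supplied genotypes
#' so the realized additive variance equals `sigma_g`.
#'
#' @param genotypes a [geno_matrix()] used to realize the genetic variance
#' @param n_qtl number of causal SNPs
#' @param h2_target narrow-sense heritability in \[0, 1\]
#' @param sigma_g target realized additive variance (phenotype units squared);
#'   default 0.9 matches the variance scale of the attachment-duration trait
#' @param effect_dist `"laplace"` (default) or `"normal"`
#' @param n_batches number of rearing batches (fixed-effect levels)
#' @param batch_sd SD of batch fixed effects (hours)
#' @param intercept overall mean attachment duration (hours)
#' @param ceiling_hours maximum recordable duration (assay length, hours)
#' @param seed integer RNG seed
#' @return an object of class `trait_architecture`.
#' @export
trait_architecture <- function(genotypes, n_qtl, h2_target = 0.40,
                               sigma_g = 0.9, effect_dist = c("laplace", "normal"),
                               n_batches = 4, batch_sd = 0.5,
                               intercept = 3.2, ceiling_hours = 6.0,
                               seed = 1L) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  m <- ncol(genotypes$dosage)
  if (n_qtl < 0 || n_qtl > m) stop("n_qtl must be in [0, m]")
  if (h2_target < 0 || h2_target > 1) stop("h2_target must be in [0, 1]")
  effect_dist <- match.arg(effect_dist)
  set.seed(seed)
  qtl <- sort(sample.int(m, n_qtl))
  eff <- if (effect_dist == "laplace") {
    # Laplace via difference of exponentials
    stats::rexp(n_qtl) - stats::rexp(n_qtl)
  } else stats::rnorm(n_qtl)
  if (n_qtl > 0 && h2_target > 0) {
    M <- genotypes$dosage[, qtl, drop = FALSE]
    M[is.na(M)] <- 0
    g <- as.vector(M %*% eff)
    vg <- stats::var(g)
    if (vg > 0) eff <- eff * sqrt(sigma_g / vg)
  }
  batch_effects <- stats::rnorm(n_batches, 0, batch_sd)
  structure(list(qtl_indices = qtl, qtl_effects = eff, h2_target = h2_target,
                 batch_effects = batch_effects, intercept = intercept,
                 ceiling_hours = ceiling_hours, seed = seed),
            class = "trait_architecture")
}

#' Simulate a censored attachment-duration phenotype
#'
#' Genetic value `g_i = sum_j effect_j * dosage_ij`; the residual variance is
#' chosen so that `Var(g) / (Var(g) + sigma_e^2)` equals `arch$h2_target` on
#' the realized sample. The phenotype is intercept + batch effect + g + e,
#' clamped to `[0, ceiling_hours]` (individuals still attached at the end of
#' the assay are recorded at the ceiling). Batches are assigned round-robin.
#'
#' @param genotypes a [geno_matrix()] (missing dosages treated as 0 copies)
#' @param arch a [trait_architecture()]
#' @param n_batches number of batches (defaults to the architecture's count)
#' @param seed integer RNG seed
#' @param censor if `FALSE`, skip the \[0, ceiling\] clamping (useful for
#'   variance-component calibration experiments)
#' @return data.frame with columns `id`, `batch`, `duration_h`, `true_bv`.
#' @export
simulate_phenotype <- function(genotypes, arch, n_batches = NULL, seed = 1L,
                               censor = TRUE) {
  stopifnot(inherits(genotypes, "geno_matrix"),
            inherits(arch, "trait_architecture"))
  if (length(arch$qtl_indices) &&
      (max(arch$qtl_indices) > ncol(genotypes$dosage) || min(arch$qtl_indices) < 1))
    stop("qtl_indices out of range for genotypes")
  if (arch$h2_target == 1 && length(arch$qtl_indices) == 0)
    stop("h2_target = 1 with zero QTLs is impossible")
  if (is.null(n_batches)) n_batches <- length(arch$batch_effects)
  set.seed(seed)
  n <- nrow(genotypes$dosage)
  if (arch$h2_target > 0 && length(arch$qtl_indices) > 0) {
    M <- genotypes$dosage[, arch$qtl_indices, drop = FALSE]
    M[is.na(M)] <- 0
    g <- as.vector(M %*% arch$qtl_effects)
    g <- g - mean(g)   # breeding values on the deviation scale; the
                       # population mean belongs to the intercept
  } else {
    g <- numeric(n)   # h2 = 0: genetic contribution exactly zero
  }
  vg <- stats::var(g)
  h2 <- arch$h2_target
  sigma_e2 <- if (h2 > 0 && vg > 0) vg * (1 - h2) / h2 else 1.0
  if (h2 == 1) sigma_e2 <- 0
  batch <- rep(seq_len(n_batches), length.out = n)
  be <- arch$batch_effects[((batch - 1) %% length(arch$batch_effects)) + 1]
  y <- arch$intercept + be + g + stats::rnorm(n, 0, sqrt(sigma_e2))
  if (censor) y <- pmin(pmax(y, 0), arch$ceiling_hours)
  data.frame(id = genotypes$ids, batch = factor(batch),
             duration_h = y, true_bv = g, stringsAsFactors = FALSE)
}

#' Mask genotype calls at random
#'
#' Each call is masked independently with probability `rate`, emulating array
#' no-calls prior to imputation.
#'
#' @param genotypes a [geno_matrix()]
#' @param rate missing probability in \[0, 1)
#' @param seed integer RNG seed
#' @return a `geno_matrix` with `realized_missing_rate` attribute.
#' @export
inject_missingness <- function(genotypes, rate, seed = 1L) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) {
    attr(genotypes, "realized_missing_rate") <- mean(is.na(genotypes$dosage))
    return(genotypes)
  }
  set.seed(seed)
  d <- genotypes$dosage
  mask <- stats::runif(length(d)) < rate
  d[mask] <- NA
  out <- geno_matrix(d, genotypes$map, ids = genotypes$ids)
  attr(out, "realized_missing_rate") <- mean(is.na(d))
  out
}

#' Summarize an attachment (drop-off) curve
#'
#' Bins detachment times into intervals of `bin_width` hours and reports the
#' per-bin drop rate (fraction of all individuals detaching in that bin), the
#' cumulative drop rate, and the final attachment rate (fraction still
#' attached at `total_hours`, i.e. recorded at the ceiling). Mass is conserved
#' exactly: cumulative drop at the last bin + final attachment = 1.
#'
#' @param durations attachment durations in hours, within \[0, total_hours\]
#' @param bin_width bin width in hours
#' @param total_hours assay length in hours
#' @return data.frame per bin: `bin_start`, `bin_end`, `drop_rate`,
#'   `cumulative_drop`; plus attribute/element `final_attachment_rate`.
#' @export
attachment_summary <- function(durations, bin_width = 1, total_hours = 6) {
  if (any(durations < 0)) stop("negative durations")
  if (any(durations > total_hours)) stop("durations exceed total_hours")
  n <- length(durations)
  n_bins <- ceiling(total_hours / bin_width)
  survived <- durations >= total_hours
  dropped <- durations[!survived]
  bin <- pmin(pmax(ceiling(dropped / bin_width), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  drop_rate <- counts / n
  out <- data.frame(
    bin_start = (seq_len(n_bins) - 1) * bin_width,
    bin_end = pmin(seq_len(n_bins) * bin_width, total_hours),
    drop_rate = drop_rate,
    cumulative_drop = cumsum(drop_rate))
  final_rate <- sum(survived) / n
  structure(list(bins = out, final_attachment_rate = final_rate,
                 n = n), class = "attachment_summary")
}

#' @export
print.attachment_summary <- function(x, ...) {
  cat(sprintf("attachment curve over %d individuals\n", x$n))
  print(x$bins, row.names = FALSE)
  cat(sprintf("final attachment rate: %.4f\n", x$final_attachment_rate))
  invisible(x)
}

#' Simulate a complete study population
#'
#' Convenience wrapper chaining [simulate_founders()], [random_mate()],
#' [trait_architecture()], [simulate_phenotype()] and [inject_missingness()]
#' with defaults emulating the study population: 400 random-mating broodstock,
#' ~1120 offspring, 18 chromosomes, 0.8% missing calls, heritability 0.40 and
#' a sparse many-minor-QTL architecture.
#'
#' @param n_founders founders (default 400)
#' @param n_offspring offspring (default 1120)
#' @param m SNP count (default 5000; the study scale of ~64788 is supported
#'   but large)
#' @param n_chrom number of chromosomes (default 18)
#' @param chrom_length per-chromosome length in bp
#' @param n_qtl causal loci (default 200)
#' @param h2_target heritability (default 0.40)
#' @param missing_rate no-call rate (default 0.008)
#' @param maf_range founder frequency interval
#' @param ld_rho LD parameter
#' @param n_batches rearing batches (default 4)
#' @param seed integer RNG seed; stage seeds are derived from it
#' @return list of class `sim_population`: `genotypes`, `phenotypes`,
#'   `true_bv`, `pedigree`, `arch`, `pool`, `seed`.
#' @export
simulate_population <- function(n_founders = 400, n_offspring = 1120,
                                m = 5000, n_chrom = 18, chrom_length = 5e7,
                                n_qtl = 200, h2_target = 0.40,
                                missing_rate = 0.008,
                                maf_range = c(0.05, 0.5), ld_rho = 0.9,
                                n_batches = 4, seed = 1L) {
  seeds <- derive_seeds(seed, c("founders", "mating", "arch", "phenotype",
                                "missing"))
  pool <- simulate_founders(n_founders, m,
                            stats::setNames(rep(chrom_length, n_chrom),
                                            paste0("chr", seq_len(n_chrom))),
                            maf_range = maf_range, ld_rho = ld_rho,
                            seed = seeds[["founders"]])
  off <- random_mate(pool, n_offspring, seed = seeds[["mating"]])
  arch <- trait_architecture(off$genotypes, n_qtl = n_qtl,
                             h2_target = h2_target, n_batches = n_batches,
                             seed = seeds[["arch"]])
  pheno <- simulate_phenotype(off$genotypes, arch, seed = seeds[["phenotype"]])
  geno <- inject_missingness(off$genotypes, missing_rate,
                             seed = seeds[["missing"]])
  structure(list(genotypes = geno, phenotypes = pheno,
                 true_bv = pheno$true_bv, pedigree = off$pedigree,
                 arch = arch, pool = pool, seed = seed),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("sim_population\n")
  print(x$genotypes)
  cat(sprintf("phenotype: mean %.2f h, sd %.2f h; h2 target %.2f; %d QTLs\n",
              mean(x$phenotypes$duration_h), stats::sd(x$phenotypes$duration_h),
              x$arch$h2_target, length(x$arch$qtl_indices)))
  invisible(x)
}

#' Derive per-stage seeds from a global seed
#'
#' Hashes each stage name with the global seed so that adding a stage never
#' perturbs the randomness of earlier stages. Results are stable across
#' platforms and stay below 2^31.
#'
#' @param seed global integer seed
#' @param stages character vector of stage names
#' @return named integer vector of derived seeds
#' @export
derive_seeds <- function(seed, stages) {
  vapply(stages, function(s) {
    h <- as.double(seed %% 2147483647L)
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    as.integer(h)
  }, integer(1))
}
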