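# Shared fixture builders. Everything is generated in code under fixed seeds;
# expensive objects are memoized per test run.

toy_geno <- function(dosage, chrom = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) {
    pos <- integer(m)
    for (cc in unique(chrom)) pos[chrom == cc] <- seq_len(sum(chrom == cc))
  }
  geno_matrix(dosage,
              data.frame(snp_id = paste0("s", seq_len(m)), chrom = chrom,
                         pos = pos, ref = "A", alt = "G",
                         stringsAsFactors = FALSE))
}

# unstructured HWE panel (no family structure)
hwe_geno <- function(n, m, seed, maf_range = c(0.05, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  d <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  toy_geno(d)
}

.fixture_env <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# a mid-sized simulated population shared across test files
shared_pop <- function() memo("pop", {
  simulate_population(n_founders = 80, n_offspring = 250, m = 800,
                      n_qtl = 60, h2_target = 0.40, missing_rate = 0.008,
                      seed = 101)
})

shared_complete <- function() memo("complete", {
  pop <- shared_pop()
  qc <- apply_qc(pop$genotypes)
  g <- impute_naive(qc$genotypes)
  ph <- pop$phenotypes[match(g$ids, pop$phenotypes$id), ]
  list(geno = g, pheno = ph, pop = pop, qc = qc)
})
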