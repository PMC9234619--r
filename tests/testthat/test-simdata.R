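test_that("founder pool honors frequency and LD settings", {
  # fixed frequency: every realized founder frequency inside an exact
  # binomial CI for p = 0.3 over 2n haplotypes
  pool <- simulate_founders(200, 300, c(chr1 = 1e6), maf_range = c(0.3, 0.3),
                            ld_rho = 0, seed = 1)
  counts <- colSums(pool$haplotypes)
  ci <- qbinom(c(1e-5, 1 - 1e-5), 400, 0.3)
  expect_true(all(counts >= ci[1] & counts <= ci[2]))
  expect_true(all(pool$haplotypes %in% c(0L, 1L)))
  for (cc in unique(pool$snp_map$chrom))
    expect_true(all(diff(pool$snp_map$pos[pool$snp_map$chrom == cc]) > 0))

  # ld_rho = 0: adjacent-site correlation ~ 0 on average
  r_adj <- sapply(1:10, function(s) {
    p <- simulate_founders(150, 200, c(chr1 = 1e6), ld_rho = 0, seed = s)
    h <- p$haplotypes
    mean(abs(diag(cor(h[, -ncol(h)], h[, -1]))), na.rm = TRUE)
  })
  # mean |r| of independent sites over 300 haplotypes ~ 0.046 (half-normal)
  expect_lt(mean(r_adj), 0.07)

  # ld_rho = 0.9: adjacent r2 well above r2 at distance 50, over seeds
  decay <- sapply(1:20, function(s) {
    p <- simulate_founders(100, 120, c(chr1 = 1e6), ld_rho = 0.9, seed = s)
    h <- p$haplotypes
    r1 <- diag(cor(h[, 1:70], h[, 2:71]))^2
    r50 <- diag(cor(h[, 1:70], h[, 51:120]))^2
    c(adj = mean(r1, na.rm = TRUE), far = mean(r50, na.rm = TRUE))
  })
  expect_gt(mean(decay["adj", ]), 3 * mean(decay["far", ]))
})

test_that("founder pool rejects invalid parameters", {
  expect_error(simulate_founders(5, 10, numeric(0)), "empty chromosome")
  expect_error(simulate_founders(5, 10, c(chr1 = 1e6), maf_range = c(0, 0.6)),
               "maf_range")
  expect_error(simulate_founders(1, 10, c(chr1 = 1e6)), "founders")
})

test_that("random mating is Mendelian and pedigree-consistent", {
  # homozygous 0/0 x 2/2 parents -> every offspring dosage 1
  m <- 20
  hap <- rbind(matrix(0L, 2, m), matrix(1L, 2, m))  # founder1 0/0, founder2 2/2
  pool <- structure(list(
    haplotypes = hap,
    snp_map = data.frame(snp_id = paste0("s", 1:m), chrom = "chr1",
                         pos = 1:m, ref = "A", alt = "G"),
    allele_freqs = rep(0.5, m), n_founders = 2, seed = 1),
    class = "founder_pool")
  off <- random_mate(pool, 30, seed = 2)
  expect_true(all(off$genotypes$dosage == 1))

  # study-scale pedigree: 1120 offspring from 400 founders
  pool2 <- simulate_founders(400, 60, c(chr1 = 1e6, chr2 = 1e6), seed = 3)
  off2 <- random_mate(pool2, 1120, seed = 4)
  expect_equal(nrow(off2$pedigree), 1120)
  expect_true(all(off2$pedigree$sire >= 0 & off2$pedigree$sire < 400))
  expect_true(all(off2$pedigree$dam >= 0 & off2$pedigree$dam < 400))
  expect_true(all(off2$pedigree$sire != off2$pedigree$dam))
  expect_true(all(off2$genotypes$dosage %in% 0:2))

  # offspring allele frequency tracks founder frequency (paired over seeds)
  diffs <- sapply(1:12, function(s) {
    p <- simulate_founders(100, 100, c(chr1 = 1e6), ld_rho = 0, seed = s)
    o <- random_mate(p, 300, seed = s + 500)
    founder_freq <- colMeans(p$haplotypes)
    mean(colMeans(o$genotypes$dosage) / 2 - founder_freq)
  })
  expect_lt(abs(mean(diffs)), 0.01)
})

test_that("phenotype simulation meets its variance contract", {
  cc <- shared_complete()
  geno <- cc$pop$genotypes

  # h2 = 0: genetic values exactly zero
  arch0 <- trait_architecture(geno, n_qtl = 50, h2_target = 0, seed = 1)
  ph0 <- simulate_phenotype(geno, arch0, seed = 2)
  expect_true(all(ph0$true_bv == 0))

  # ceiling respected; batches round-robin
  arch <- trait_architecture(geno, n_qtl = 50, h2_target = 0.4, seed = 1)
  ph <- simulate_phenotype(geno, arch, seed = 2)
  expect_lte(max(ph$duration_h), arch$ceiling_hours)
  expect_gte(min(ph$duration_h), 0)
  bt <- table(ph$batch)
  expect_equal(length(bt), 4L)
  expect_lte(max(bt) - min(bt), 1)

  # contract: realized Var(g) hits the architecture target exactly; the
  # realized variance ratio then matches h2 up to residual sampling noise
  # (CV of var(e) ~ sqrt(2/n) ~ 9% at n = 250)
  expect_equal(var(ph$true_bv), 0.9, tolerance = 1e-9)
  ph_raw <- simulate_phenotype(geno, arch, seed = 2, censor = FALSE)
  resid <- ph_raw$duration_h - ph_raw$true_bv
  vr <- var(ph_raw$true_bv) / (var(ph_raw$true_bv) + var(resid))
  expect_equal(vr, 0.4, tolerance = 0.2)

  # impossible contract
  arch_bad <- trait_architecture(geno, n_qtl = 0, h2_target = 1, seed = 1)
  expect_error(simulate_phenotype(geno, arch_bad), "impossible")
})

test_that("missingness injection is binomial and identity at rate 0", {
  cc <- shared_pop()
  g <- cc$genotypes
  expect_identical(inject_missingness(g, 0, seed = 1)$dosage, g$dosage)

  big <- hwe_geno(1120, 10000, seed = 5)
  out <- inject_missingness(big, 0.008, seed = 6)
  realized <- attr(out, "realized_missing_rate")
  sd3 <- 3 * sqrt(0.008 * 0.992 / length(big$dosage))
  expect_lt(abs(realized - 0.008), sd3)

  toy <- toy_geno(matrix(1, 4, 4))
  masked <- sum(is.na(inject_missingness(toy, 0.5, seed = 7)$dosage))
  expect_gte(masked, qbinom(0.0005, 16, 0.5))
  expect_lte(masked, qbinom(0.9995, 16, 0.5))
  expect_error(inject_missingness(toy, 1), "rate")
})

test_that("attachment summary conserves mass and matches hand counts", {
  s <- attachment_summary(c(0.5, 1.5, 2.5, 6.0), bin_width = 1, total_hours = 6)
  expect_equal(s$bins$drop_rate, c(0.25, 0.25, 0.25, 0, 0, 0))
  expect_equal(s$final_attachment_rate, 0.25)

  s2 <- attachment_summary(rep(6, 10), 1, 6)
  expect_equal(s2$final_attachment_rate, 1.0)
  expect_true(all(s2$bins$drop_rate == 0))

  expect_error(attachment_summary(c(-1, 2)), "negative")

  for (s in 1:20) {
    set.seed(s)
    dur <- pmin(rexp(50, 1 / 3), 6)
    a <- attachment_summary(dur, 1, 6)
    expect_true(all(diff(a$bins$cumulative_drop) >= 0))
    # mass conservation (exact in counts; 1 ulp slack for the division)
    expect_equal(a$bins$cumulative_drop[6] + a$final_attachment_rate, 1,
                 tolerance = 1e-15)
  }
})

test_that("same seed gives byte-identical datasets", {
  a <- simulate_population(n_founders = 30, n_offspring = 50, m = 200,
                           n_qtl = 20, seed = 42)
  b <- simulate_population(n_founders = 30, n_offspring = 50, m = 200,
                           n_qtl = 20, seed = 42)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$pedigree, b$pedigree)
  c <- simulate_population(n_founders = 30, n_offspring = 50, m = 200,
                           n_qtl = 20, seed = 43)
  expect_false(identical(a$genotypes$dosage, c$genotypes$dosage))
})
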