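test_that("significance thresholds reproduce the Bonferroni arithmetic", {
  thr <- compute_thresholds(64788, 0.05)
  expect_equal(thr$genome_wide_p, 7.72e-07, tolerance = 1e-3)
  expect_identical(unname(thr$neglog10["genome_wide"]), 6.11)
  expect_identical(unname(thr$neglog10["suggestive"]), 5)
  expect_equal(compute_thresholds(1, 0.05)$genome_wide_p, 0.05)
  expect_error(compute_thresholds(0), "m_tests")
})

test_that("classification respects the boundary convention and monotonicity", {
  thr <- compute_thresholds(64788, 0.05)
  rep_snps <- reported_gwas_snps()
  cls <- classify_snps(rep_snps, thr)
  expect_equal(unname(cls$counts["genome_wide"]), 11L)
  expect_equal(unname(cls$counts["suggestive"]), 2L)

  allp1 <- data.frame(p_value = rep(1, 5))
  expect_equal(unname(classify_snps(allp1, thr)$counts[c(1, 2)]), c(0L, 0L))

  # p exactly at a threshold passes it
  edge <- data.frame(p_value = c(thr$genome_wide_p, thr$suggestive_p))
  ce <- classify_snps(edge, thr)
  expect_equal(ce$table$class, c("genome-wide", "suggestive"))

  # loosening the suggestive threshold never reduces labeled SNPs
  set.seed(5)
  p <- runif(500)^3
  labeled <- sapply(c(1e-5, 1e-3, 1e-1), function(sg) {
    ct <- classify_snps(data.frame(p_value = p),
                        compute_thresholds(500, 0.05, suggestive = sg))$counts
    sum(ct[c("genome_wide", "suggestive")])
  })
  expect_true(all(diff(labeled) >= 0))
})

test_that("PVE formula and worked arithmetic", {
  expect_equal(compute_pve(0, 0.3, 2), 0)
  expect_equal(compute_pve(1, 0.5, 2), 25)   # 100 * 2*0.25*1 / 2
  expect_error(compute_pve(1, 0.5, 0), "var_p")
  # the 13 reported PVE values sum to 8.22%
  expect_equal(sum(reported_gwas_snps()$pve), 8.22, tolerance = 1e-9)
})

test_that("EMMAX scan equals OLS at zero variance ratio", {
  cc <- shared_complete()
  set.seed(99)
  y <- rnorm(nrow(cc$geno$dosage))
  grm <- grm_vanraden(cc$geno)
  nf <- fit_null_mlm(y, NULL, grm, fix_lambda = 0)
  sc <- scan_association(cc$geno, y, null_fit = nf)
  idx <- seq_len(40)
  p_ols <- apply(cc$geno$dosage[, idx], 2, function(g)
    summary(lm(y ~ g))$coefficients[2, 4])
  expect_lt(max(abs(sc$p_value[idx] - unname(p_ols))), 1e-6)
})

test_that("scan is invariant to allele relabeling and flags monomorphic SNPs", {
  cc <- shared_complete()
  ph <- cc$pheno
  g <- cc$geno
  grm <- grm_vanraden(g)
  X <- model.matrix(~ batch, ph)
  nf <- fit_null_mlm(ph$duration_h, X, grm)
  sc <- scan_association(g, ph$duration_h, null_fit = nf)
  gflip <- geno_matrix(2 - g$dosage,
                       transform(g$map, ref = g$map$alt, alt = g$map$ref),
                       g$ids)
  # GRM identical under flip, so the same null fit applies
  sc2 <- scan_association(gflip, ph$duration_h, null_fit = nf)
  expect_equal(sc$p_value, sc2$p_value, tolerance = 1e-9)
  # minor-allele orientation is well defined away from the MAF = 0.5 tie
  untied <- sc$maf < 0.499
  expect_equal(sc$beta[untied], sc2$beta[untied], tolerance = 1e-9)
  expect_equal(sc$minor_allele[untied], sc2$minor_allele[untied])

  # monomorphic column
  d <- g$dosage; d[, 3] <- 2
  gm <- geno_matrix(d, g$map, g$ids)
  sc3 <- scan_association(gm, ph$duration_h, null_fit = nf)
  expect_true(sc3$monomorphic[3])
  expect_identical(sc3$p_value[3], 1)
  expect_identical(sc3$beta[3], 0)
})

test_that("scan ranks a planted strong QTL at the top", {
  hits <- sapply(1:5, function(s) {
    pop <- simulate_population(n_founders = 80, n_offspring = 500, m = 1000,
                               n_qtl = 40, h2_target = 0.35,
                               missing_rate = 0, seed = s)
    g <- pop$genotypes
    # plant one QTL explaining ~5% of phenotypic variance
    set.seed(s)
    j <- sample(ncol(g$dosage), 1)
    x <- g$dosage[, j]
    y <- pop$phenotypes$duration_h
    b <- sqrt(0.05 * var(y) / max(var(x), 1e-8))
    y2 <- y + b * x
    nf <- fit_null_mlm(y2, NULL, grm_vanraden(g))
    sc <- scan_association(g, y2, null_fit = nf)
    rank(sc$p_value)[j] <= 0.01 * nrow(sc)
  })
  expect_gte(sum(hits), 4)
})

test_that("candidate-gene annotation measures distances on a toy GFF3", {
  gff <- tempfile(fileext = ".gff3")
  write_gff3(data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000, 50000, 100),
    end   = c(2000, 60000, 200),
    gene_id = c("geneA", "geneB", "geneC")), gff)
  snps <- data.frame(snp_id = c("in_gene", "near", "lonely"),
                     chrom = c("chr1", "chr1", "chr3"),
                     pos = c(1500, 70000, 5))
  ann <- annotate_candidates(snps, gff, window_bp = 50000)
  # SNP at chr1:1500 overlaps geneA (distance 0) and geneB's boundary is
  # also inside the 50 kb window (distance 48500): both reported
  ing <- ann[ann$snp_id == "in_gene", ]
  expect_setequal(ing$gene_id, c("geneA", "geneB"))
  expect_equal(ing$distance_bp[ing$gene_id == "geneA"], 0)
  expect_true(all(ing$region == "genic"))
  near <- ann[ann$snp_id == "near", ]
  expect_true("geneB" %in% near$gene_id)
  expect_equal(near$distance_bp[near$gene_id == "geneB"], 10000)
  lonely <- ann[ann$snp_id == "lonely", ]
  expect_true(is.na(lonely$gene_id))
  expect_false(lonely$within_window)
  expect_equal(attr(ann, "unmatched_chromosomes"), "chr3")
})

test_that("Manhattan/QQ export follows the plotting conventions", {
  res <- data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
                    pos = c(10, 20, 30), p_value = c(0.5, 0.05, 0.005))
  mq <- export_manhattan_qq(res)
  # single chromosome: x equals raw position
  expect_equal(mq$manhattan$x, res$pos)
  expect_equal(mq$qq$expected, -log10((1:3 - 0.5) / 3))
  expect_equal(mq$qq$observed, sort(-log10(res$p_value), decreasing = TRUE))

  res2 <- rbind(res, data.frame(snp_id = "d", chrom = "chr2", pos = 7,
                                p_value = 0.1))
  mq2 <- export_manhattan_qq(res2)
  expect_equal(mq2$manhattan$x[4], 30 + 7)   # offset by chr1 max position
})
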