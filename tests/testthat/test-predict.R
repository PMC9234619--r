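test_that("heritability arithmetic reproduces the published worked examples", {
  h1 <- heritability(0.92, 1.26)
  expect_equal(h1$sigma_p2, 2.18)
  expect_equal(round(h1$h2, 2), 0.42)
  h2 <- heritability(0.89, 1.65)
  expect_equal(h2$sigma_p2, 2.54)
  expect_equal(round(h2$h2, 2), 0.35)
  expect_equal(heritability(0, 3)$h2, 0)
  expect_error(heritability(0, 0), "undefined")
  expect_error(heritability(-1, 2), ">= 0")
  vc <- variance_components(0.92, 1.26, method = "GBLUP-REML")
  expect_identical(vc$sigma_p2, vc$sigma_g2 + vc$sigma_e2)
})

test_that("REML finds no genetic variance in null data", {
  # 20 seeds: the 10-seed mean of this boundary-censored estimator has a
  # Monte-Carlo SD of ~0.01, too close to the 0.05 bound to be stable
  h2s <- sapply(1:20, function(s) {
    g <- hwe_geno(500, 1000, seed = 200 + s)
    set.seed(300 + s)
    y <- rnorm(500, 3, 1.5)
    fit <- gblup_reml(y, NULL, grm_vanraden(g))
    fit$varcomp$h2
  })
  expect_lt(mean(h2s), 0.05)
})

test_that("GBLUP recovers simulated heritability and shrinks", {
  cc <- shared_complete()
  X <- model.matrix(~ batch, cc$pheno)
  grm <- grm_vanraden(cc$geno)
  fit <- gblup_reml(cc$pheno$duration_h, X, grm)
  expect_gt(fit$varcomp$h2, 0.15)
  expect_lt(fit$varcomp$h2, 0.65)
  expect_gt(cor(fit$gebv, cc$pheno$true_bv), 0.5)
  # shrinkage direction
  expect_lte(var(fit$gebv), fit$varcomp$sigma_g2 * mean(diag(grm$matrix)))
  # intercept absorbs constant shifts
  fit2 <- gblup_reml(cc$pheno$duration_h + 100, X, grm)
  expect_equal(fit$gebv, fit2$gebv, tolerance = 1e-6)
})

test_that("masked prediction agrees with a hand-solved Henderson system", {
  g <- hwe_geno(6, 40, seed = 77)
  grm <- grm_vanraden(g, ridge = 1e-3)   # invertible G for the MME oracle
  G <- grm$matrix
  X <- cbind(1, c(0, 0, 0, 1, 1, 1))    # intercept + one batch contrast
  set.seed(78)
  y <- as.vector(X %*% c(3, 0.5)) + rnorm(6, 0, 1)
  sg2 <- 0.5; se2 <- 1.0
  model <- structure(list(y = y, X = X, G = G,
                          varcomp = variance_components(sg2, se2)),
                     class = "gblup_fit")
  test <- c(5L, 6L)
  train <- 1:4
  # independent oracle: Henderson MME over all individuals, Z maps the 4
  # phenotyped (training) records onto the 6 genetic effects
  Z <- diag(6)[train, ]
  Xt <- X[train, , drop = FALSE]
  LHS <- rbind(cbind(crossprod(Xt), t(Xt) %*% Z),
               cbind(t(Z) %*% Xt, crossprod(Z) + solve(G) * (se2 / sg2)))
  RHS <- c(crossprod(Xt, y[train]), t(Z) %*% y[train])
  sol <- solve(LHS, RHS)
  g_oracle <- sol[3:8]
  pred <- gblup_predict(model, test_ids = test)
  expect_lt(max(abs(pred - g_oracle)), 1e-10)

  # no masking -> in-sample BLUP from the fitted model
  grm2 <- grm_vanraden(hwe_geno(30, 100, seed = 79))
  set.seed(80); y2 <- rnorm(30, 3, 1)
  fit <- gblup_reml(y2, NULL, grm2)
  expect_identical(gblup_predict(fit, integer(0)), fit$gebv)
  expect_error(gblup_predict(fit, 1:30), "all individuals")

  # duplicate row in G -> identical GEBV for the pair
  d <- hwe_geno(8, 60, seed = 81)$dosage
  d[8, ] <- d[1, ]
  Gd <- grm_vanraden(d)$matrix
  set.seed(82); yd <- rnorm(8, 3, 1); yd[8] <- yd[1]
  md <- structure(list(y = yd, X = matrix(1, 8, 1), G = Gd,
                       varcomp = variance_components(0.5, 1)),
                  class = "gblup_fit")
  pd <- gblup_predict(md, test_ids = 8L)   # ind 8 is a genomic copy of ind 1
  expect_equal(unname(pd[8]), unname(pd[1]), tolerance = 1e-10)
})

test_that("BayesB spike, determinism and ridge equivalence", {
  cc <- shared_complete()
  y <- cc$pheno$duration_h
  X <- model.matrix(~ batch, cc$pheno)
  M <- cc$geno$dosage[, 1:200]

  # pi = 1: every effect exactly zero, GEBV all zero
  b1 <- bayesb_gibbs(y, X, M, pi = 1, n_iter = 300, burn_in = 50, seed = 1)
  expect_true(all(b1$u == 0))
  expect_true(all(b1$gebv == 0))
  expect_true(all(b1$inclusion_prob == 0))

  # fixed seed -> bit-identical chains
  b2 <- bayesb_gibbs(y, X, M, pi = 0.95, n_iter = 400, burn_in = 100, seed = 9)
  b3 <- bayesb_gibbs(y, X, M, pi = 0.95, n_iter = 400, burn_in = 100, seed = 9)
  expect_identical(b2$u, b3$u)
  expect_identical(b2$sigma_e2, b3$sigma_e2)

  # pi = 0 with fixed locus variance = Bayesian ridge = GBLUP (matched
  # variance), scaled-down instance of the equivalence oracle
  g <- hwe_geno(150, 300, seed = 55)
  set.seed(56)
  u_true <- rnorm(300, 0, 0.05)
  yb <- 3 + as.vector(scale(g$dosage, scale = FALSE) %*% u_true) + rnorm(150, 0, 1)
  grm <- grm_vanraden(g)
  fit <- gblup_reml(yb, NULL, grm)
  S <- fit$varcomp$sigma_g2 / sum(2 * grm$allele_freqs * (1 - grm$allele_freqs))
  bb <- bayesb_gibbs(yb, NULL, g$dosage, pi = 0, nu = Inf, S = S,
                     n_iter = 3000, burn_in = 500, seed = 57)
  expect_gt(cor(fit$gebv, bb$gebv), 0.99)

  expect_error(bayesb_gibbs(y, X, M, n_iter = 100, burn_in = 100), "burn_in")
  expect_error(bayesb_gibbs(y, X, M, S = -1, n_iter = 200, burn_in = 50),
               "S")
})

test_that("BayesB beats GBLUP on sparse architectures, not on polygenic ones", {
  # scaled-down: single 80/20 split, 6 seeds per architecture
  advantage <- function(n_qtl, seeds) sapply(seeds, function(s) {
    pop <- simulate_population(n_founders = 80, n_offspring = 250, m = 600,
                               n_qtl = n_qtl, h2_target = 0.4,
                               missing_rate = 0, seed = s)
    ph <- pop$phenotypes; y <- ph$duration_h
    X <- model.matrix(~ batch, ph)
    set.seed(s); test <- sample(250, 50); train <- setdiff(1:250, test)
    d <- pop$genotypes$dosage
    G <- grm_vanraden(d)$matrix
    fit <- gblup_reml(y[train], X[train, ], G[train, train])
    Vtt <- fit$varcomp$sigma_g2 * G[train, train]
    diag(Vtt) <- diag(Vtt) + fit$varcomp$sigma_e2 + 1e-6
    a <- solve(Vtt, y[train] - fit$X %*% fit$beta)
    acc_g <- cor(y[test], as.vector(fit$varcomp$sigma_g2 *
                                      G[test, train] %*% a))
    bb <- bayesb_gibbs(y[train], X[train, ], d[train, ], pi = 0.95,
                       n_iter = 3000, burn_in = 500, seed = s)
    acc_b <- cor(y[test], bayesb_predict(bb, d[test, ]))
    acc_b - acc_g
  })
  sparse <- advantage(10, 1:6)
  poly <- advantage(500, 1:6)
  expect_gt(mean(sparse), 0)
  expect_gt(mean(sparse), mean(poly))
})
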