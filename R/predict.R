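# GBLUP via eigen-rotation REML.
#
# Model: y = X b + g + e, g ~ N(0, G sigma_g2), e ~ N(0, I sigma_e2).
# With G = U D U', the rotated model has diagonal covariance
# sigma_e2 * (lambda * d_i + 1), lambda = sigma_g2 / sigma_e2, so the REML
# log-likelihood profiles to a 1-D function of lambda. Exact for a single
# random effect; derivative-free maximization on log(lambda).

reml_profile <- function(loglambda, d, ys, Xs, n, p) {
  delta <- exp(loglambda) * d + 1
  w <- 1 / delta
  XtWX <- crossprod(Xs * w, Xs)
  XtWy <- crossprod(Xs * w, ys)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- ys - Xs %*% beta
  rss <- sum(w * r^2)
  sigma_e2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(sigma_e2) + sum(log(delta)) +
                  2 * sum(log(diag(ch))) + (n - p))
  ll
}

#' GBLUP variance components and breeding values by REML
#'
#' Fits `y = X b + g + e` with `g ~ N(0, G sigma_g2)` by restricted maximum
#' likelihood, using the eigendecomposition of `G` and 1-D optimization of
#' the profile likelihood over the variance ratio. Returns variance
#' components (with approximate standard errors from the numerical Hessian),
#' heritability, fixed-effect estimates and GEBVs for all individuals.
#'
#' A small ridge (default 1e-6) is added to the GRM diagonal so the rotated
#' system is always well conditioned. A `sigma_g2` estimate at the lower
#' boundary is returned with `boundary = TRUE`, not an error.
#'
#' @param y numeric phenotype vector
#' @param X fixed-effect design matrix (intercept, batch, ...); a vector of
#'   ones is used when `NULL`
#' @param grm a [grm_vanraden()] result (or plain symmetric matrix)
#' @param ridge diagonal ridge added before decomposition
#' @param tol convergence tolerance on the profile optimum
#' @param max_iter maximum optimizer evaluations (safety cap)
#' @param fix_lambda optional fixed variance ratio `sigma_g2 / sigma_e2`
#'   (skips REML; `0` collapses the model to ordinary least squares)
#' @return object of class `gblup_fit`: `varcomp` (a `variance_components`),
#'   `beta`, `gebv`, `lambda`, `loglik`, `boundary`, plus the data needed for
#'   prediction (`y`, `X`, `G`, eigen cache).
#' @export
gblup_reml <- function(y, X = NULL, grm, ridge = 1e-6, tol = 1e-8,
                       max_iter = 200, fix_lambda = NULL) {
  G <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
  n <- length(y)
  stopifnot(nrow(G) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- qr(X)$rank
  if (n <= p) stop("need n > rank(X)")
  if (ridge > 0) {
    G <- G
    diag(G) <- diag(G) + ridge
  }
  e <- eigen(G, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  f <- function(ll) reml_profile(ll, d, ys, Xs, n, p)
  boundary <- FALSE
  if (!is.null(fix_lambda)) {
    lambda <- fix_lambda
    loglik <- f(if (lambda > 0) log(lambda) else -30)
    boundary <- lambda == 0
  } else {
    opt <- stats::optimize(f, interval = c(-14, 14), maximum = TRUE,
                           tol = max(tol, 1e-10))
    # compare against the no-genetic-variance boundary
    ll0 <- f(-30)
    if (ll0 >= opt$objective - 1e-10 || opt$maximum <= -13.5) {
      lambda <- 0; loglik <- ll0; boundary <- TRUE
    } else {
      lambda <- exp(opt$maximum); loglik <- opt$objective
    }
  }

  delta <- lambda * d + 1
  w <- 1 / delta
  XtWX <- crossprod(Xs * w, Xs)
  beta <- solve(XtWX, crossprod(Xs * w, ys))
  r <- ys - Xs %*% beta
  sigma_e2 <- sum(w * r^2) / (n - p)
  sigma_g2 <- lambda * sigma_e2

  # GEBV: BLUP of g given variance components
  gw <- sigma_g2 * d / (sigma_g2 * d + sigma_e2)
  gebv <- as.vector(U %*% (gw * r))
  names(gebv) <- rownames(G)

  se <- varcomp_se(d, ys, Xs, n, p, sigma_g2, sigma_e2)
  vc <- variance_components(sigma_g2, sigma_e2, method = "GBLUP-REML",
                            se_g = se["sigma_g2"], se_e = se["sigma_e2"],
                            se_h2 = se["h2"])
  structure(list(varcomp = vc, beta = as.vector(beta), gebv = gebv,
                 lambda = lambda, loglik = loglik, boundary = boundary,
                 y = y, X = X, G = G, eigen = list(U = U, d = d)),
            class = "gblup_fit")
}

# REML log-likelihood in the (sigma_g2, sigma_e2) parametrization, for the
# numerical Hessian behind the standard errors.
reml_ll_sg_se <- function(sg2, se2, d, ys, Xs, n, p) {
  delta <- sg2 * d + se2
  if (any(delta <= 0)) return(-Inf)
  w <- 1 / delta
  XtWX <- crossprod(Xs * w, Xs)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs * w, ys)))
  r <- ys - Xs %*% beta
  -0.5 * (sum(log(delta)) + 2 * sum(log(diag(ch))) + sum(w * r^2))
}

varcomp_se <- function(d, ys, Xs, n, p, sg2, se2) {
  out <- c(sigma_g2 = NA_real_, sigma_e2 = NA_real_, h2 = NA_real_)
  if (sg2 <= 0) return(out)
  f <- function(th) reml_ll_sg_se(th[1], th[2], d, ys, Xs, n, p)
  H <- tryCatch(stats::optimHess(c(sg2, se2), f), error = function(e) NULL)
  if (is.null(H)) return(out)
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V) || any(diag(V) < 0)) return(out)
  out["sigma_g2"] <- sqrt(V[1, 1])
  out["sigma_e2"] <- sqrt(V[2, 2])
  tot <- sg2 + se2
  grad <- c(se2, -sg2) / tot^2      # delta method for h2 = sg2/(sg2+se2)
  out["h2"] <- sqrt(drop(t(grad) %*% V %*% grad))
  out
}

#' Variance components and heritability container
#'
#' @param sigma_g2 additive genetic variance (>= 0)
#' @param sigma_e2 residual variance (>= 0)
#' @param method method tag, e.g. `"GBLUP-REML"` or `"BayesB-MCMC"`
#' @param se_g,se_e,se_h2 optional standard errors
#' @return object of class `variance_components` with `sigma_p2` and `h2`
#'   computed as `sigma_g2 + sigma_e2` and `sigma_g2 / sigma_p2`.
#' @export
variance_components <- function(sigma_g2, sigma_e2, method = "unknown",
                                se_g = NA, se_e = NA, se_h2 = NA) {
  h <- heritability(sigma_g2, sigma_e2)
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 sigma_p2 = h$sigma_p2, h2 = h$h2, method = method,
                 se = c(sigma_g2 = unname(se_g), sigma_e2 = unname(se_e),
                        h2 = unname(se_h2))),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("%s: sigma_g2=%.4f sigma_e2=%.4f sigma_p2=%.4f h2=%.4f\n",
              x$method, x$sigma_g2, x$sigma_e2, x$sigma_p2, x$h2))
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' `sigma_p2 = sigma_g2 + sigma_e2`; `h2 = sigma_g2 / sigma_p2`.
#'
#' @param sigma_g2 additive genetic variance (>= 0)
#' @param sigma_e2 residual variance (>= 0)
#' @param digits optional rounding applied to the reported h2
#' @return list with `sigma_p2` and `h2`
#' @export
heritability <- function(sigma_g2, sigma_e2, digits = NULL) {
  if (sigma_g2 < 0 || sigma_e2 < 0) stop("variance components must be >= 0")
  if (sigma_g2 == 0 && sigma_e2 == 0) stop("both components zero: h2 undefined")
  sigma_p2 <- sigma_g2 + sigma_e2
  h2 <- sigma_g2 / sigma_p2
  if (!is.null(digits)) h2 <- round(h2, digits)
  list(sigma_p2 = sigma_p2, h2 = h2)
}

#' GEBVs with a held-out test set (mask-and-predict)
#'
#' Re-solves the mixed-model equations using training phenotypes only (test
#' phenotypes treated as missing) at the model's variance components, and
#' recovers test GEBVs through the training-test covariance block of `G`.
#' With an empty test set this reproduces the in-sample BLUP.
#'
#' @param model a [gblup_reml()] fit carrying the full cohort
#' @param test_ids integer indices (or logical vector) of individuals whose
#'   phenotypes are masked
#' @return numeric GEBV vector for all individuals
#' @export
gblup_predict <- function(model, test_ids = integer(0)) {
  stopifnot(inherits(model, "gblup_fit"))
  n <- length(model$y)
  if (is.logical(test_ids)) test_ids <- which(test_ids)
  if (length(test_ids) >= n) stop("test set cannot include all individuals")
  if (length(test_ids) == 0) return(model$gebv)
  train <- setdiff(seq_len(n), test_ids)
  sg2 <- model$varcomp$sigma_g2; se2 <- model$varcomp$sigma_e2
  Gtt <- model$G[train, train, drop = FALSE]
  Vtt <- sg2 * Gtt
  diag(Vtt) <- diag(Vtt) + se2
  Xt <- model$X[train, , drop = FALSE]
  yt <- model$y[train]
  Vinv_X <- solve(Vtt, Xt)
  beta <- solve(crossprod(Xt, Vinv_X), crossprod(Vinv_X, yt))
  resid <- yt - Xt %*% beta
  a <- solve(Vtt, resid)
  gebv <- as.vector(sg2 * model$G[, train, drop = FALSE] %*% a)
  names(gebv) <- rownames(model$G)
  gebv
}

#' BayesB marker-effect regression by Gibbs sampling
#'
#' Spike-and-slab prior: each SNP effect is zero with probability `pi`, else
#' normal with a locus-specific variance carrying a scaled-inverse-chi-square
#' prior (df `nu`, scale `S`). Full Gibbs scheme: fixed effects from their
#' normal conditionals; per-SNP inclusion indicator from the marginal
#' likelihood ratio (effect integrated out), then the effect from its normal
#' conditional and the locus variance from its scaled-inverse-chi-square
#' conditional; the residual variance from its inverse-chi-square
#' conditional. `nu = Inf` freezes every locus variance at `S`, which with
#' `pi = 0` makes the sampler an exact Bayesian ridge (RR-BLUP), the
#' GBLUP-equivalence oracle.
#'
#' Genotype columns are centered internally; GEBVs are `M_c \%*\% E[u]`.
#'
#' @param y phenotype vector
#' @param X fixed-effect design (default intercept only)
#' @param M genotype dosage matrix (0/1/2 copies of the counted allele)
#' @param pi prior null probability (default 0.95)
#' @param n_iter,burn_in,thin chain controls. Defaults follow the "fast"
#'   profile (5000/500); use [chain_profile()]`("paper")` for 100000/3000.
#' @param nu prior df for locus variances (default 5; `Inf` = fixed at `S`)
#' @param S prior scale; when `NULL`, chosen so the prior mean marker
#'   variance corresponds to an assumed h2 of 0.5 spread over the non-null
#'   fraction of markers
#' @param seed integer RNG seed (chains are bit-reproducible under it)
#' @param keep_trace if `TRUE`, return thinned traces of `sigma_e2` and the
#'   genetic variance for diagnostics
#' @return object of class `bayesb_fit`: posterior means `b`, `u`,
#'   `inclusion_prob`, `sigma_e2`, `gebv`, `varcomp` (sigma_g2 defined as
#'   `Var(M_c E[u])`; `sigma_g2_mcmc` is the posterior-mean per-iteration
#'   genetic variance, kept for diagnostics), and the centering vector.
#' @export
bayesb_gibbs <- function(y, X = NULL, M, pi = 0.95, n_iter = 5000,
                         burn_in = 500, thin = 1, nu = 5, S = NULL,
                         seed = 1L, keep_trace = FALSE) {
  n <- length(y)
  M <- as.matrix(M)
  stopifnot(nrow(M) == n)
  if (pi < 0 || pi > 1) stop("pi must be in [0, 1]")
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  cm <- colMeans(M)
  Mc <- sweep(M, 2, cm)
  p2pq <- sum(2 * (cm / 2) * (1 - cm / 2))
  vy <- stats::var(y)
  if (is.null(S)) {
    h2_assumed <- 0.5
    frac <- max(1 - pi, 1 / ncol(M))
    denom <- max(frac * p2pq, .Machine$double.eps)
    S <- if (is.finite(nu) && nu > 2) {
      vy * h2_assumed / denom * (nu - 2) / nu
    } else vy * h2_assumed / denom
  }
  if (!is.finite(S) || S <= 0)
    stop("degenerate prior scale S; check hyperparameters")
  set.seed(seed)
  fit <- bayesb_gibbs_cpp(y, X, Mc, pi, as.integer(n_iter),
                          as.integer(burn_in), as.integer(thin),
                          ifelse(is.finite(nu), nu, -1), S,
                          keep_trace)
  gebv <- as.vector(Mc %*% fit$u_mean)
  sigma_g2 <- stats::var(gebv)
  vc <- variance_components(sigma_g2, fit$sigma_e2_mean,
                            method = "BayesB-MCMC")
  structure(list(b = as.vector(fit$b_mean), u = as.vector(fit$u_mean),
                 inclusion_prob = as.vector(fit$delta_mean),
                 sigma_e2 = fit$sigma_e2_mean,
                 sigma_g2_mcmc = fit$gvar_mean,
                 gebv = gebv, varcomp = vc, center = cm, pi = pi,
                 nu = nu, S = S,
                 trace = if (keep_trace) list(sigma_e2 = fit$trace_se2,
                                              sigma_g2 = fit$trace_gvar)),
            class = "bayesb_fit")
}

#' Predict GEBVs for new individuals from a BayesB fit
#'
#' @param fit a [bayesb_gibbs()] fit
#' @param M_new dosage matrix for the individuals to predict (same SNPs,
#'   same coding); centered with the training means
#' @return numeric GEBV vector
#' @export
bayesb_predict <- function(fit, M_new) {
  stopifnot(inherits(fit, "bayesb_fit"))
  M_new <- as.matrix(M_new)
  as.vector(sweep(M_new, 2, fit$center) %*% fit$u)
}

#' Chain-length profiles
#'
#' `"fast"` (tests and smoke runs): 5000 iterations, 500 burn-in.
#' `"paper"` (study-faithful): 100000 iterations, 3000 burn-in.
#'
#' @param profile `"fast"` or `"paper"`
#' @return list with `n_iter` and `burn_in`
#' @export
chain_profile <- function(profile = c("fast", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper") list(n_iter = 100000L, burn_in = 3000L)
  else list(n_iter = 5000L, burn_in = 500L)
}
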