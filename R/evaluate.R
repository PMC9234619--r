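# Cross-validation harness and the SNP-panel experiment grid.

#' Build a repeated k-fold plan
#'
#' Uniform random partitions; within every repeat the folds are disjoint,
#' exhaustive and balanced (sizes differ by at most 1). Deterministic under
#' the seed.
#'
#' @param n number of individuals
#' @param k folds per repeat (default 5)
#' @param repeats number of repeats (default 10)
#' @param seed integer RNG seed
#' @return object of class `fold_plan` with `assignment`
#'   (repeats x n integer matrix of fold ids)
#' @export
make_folds <- function(n, k = 5, repeats = 10, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("n must be >= k")
  set.seed(seed)
  assignment <- t(vapply(seq_len(repeats), function(r) {
    sample(rep_len(seq_len(k), n))
  }, integer(n)))
  structure(list(n = n, k = k, repeats = repeats, seed = seed,
                 assignment = assignment), class = "fold_plan")
}

#' Prediction accuracy: Pearson correlation of phenotype and GEBV
#'
#' @param y_test observed phenotypes in the test set (>= 3 values)
#' @param gebv_test predicted GEBVs
#' @return Pearson r
#' @export
accuracy <- function(y_test, gebv_test) {
  if (length(y_test) < 3) stop("need at least 3 pairs")
  if (stats::sd(y_test) == 0 || stats::sd(gebv_test) == 0)
    stop("zero variance: accuracy undefined")
  stats::cor(y_test, gebv_test)
}

#' Prediction bias: regression of phenotype on GEBV
#'
#' `b1 = cov(y, gebv) / var(gebv)`. A coefficient below (above) 1 indicates
#' GEBVs over- (under-) estimate the spread of breeding values.
#'
#' @param y_test observed phenotypes
#' @param gebv_test predicted GEBVs
#' @return regression coefficient b1
#' @export
bias <- function(y_test, gebv_test) {
  v <- stats::var(gebv_test)
  if (v == 0) stop("zero GEBV variance: bias undefined")
  stats::cov(y_test, gebv_test) / v
}

#' Specify a SNP panel
#'
#' @param mode `"top_gwas"` (smallest p-values first, ties broken by
#'   chromosome then position), `"random"` (uniform without replacement) or
#'   `"all"`
#' @param size panel size (ignored for `"all"`)
#' @param seed RNG seed for random mode
#' @return a `panel_spec` object
#' @export
panel_spec <- function(mode = c("top_gwas", "random", "all"), size = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode != "all" && (is.null(size) || size < 1))
    stop("size required for mode ", mode)
  structure(list(mode = mode, size = size, seed = seed), class = "panel_spec")
}

#' Select a SNP panel
#'
#' @param gwas_results an `assoc_result` covering all candidate SNPs (needed
#'   for `top_gwas`; for `random`/`all` only the SNP count/order is used)
#' @param spec a [panel_spec()]
#' @return sorted integer vector of SNP column indices
#' @export
build_panel <- function(gwas_results, spec) {
  stopifnot(inherits(spec, "panel_spec"))
  m <- nrow(gwas_results)
  if (spec$mode == "all") return(seq_len(m))
  if (spec$size > m) stop("panel size ", spec$size, " exceeds available ", m)
  if (spec$mode == "top_gwas") {
    ord <- order(gwas_results$p_value, gwas_results$chrom, gwas_results$pos)
    return(sort(ord[seq_len(spec$size)]))
  }
  set.seed(spec$seed)
  sort(sample.int(m, spec$size))
}

#' Run the cross-validated model x panel experiment grid
#'
#' For every (model, panel) cell and every repeat/fold: restrict genotypes to
#' the panel, train on the training folds only, predict GEBVs for the test
#' fold, and record the Pearson accuracy per fold and the regression bias per
#' repeat (pooled over that repeat's out-of-fold predictions). With
#' `leakage_mode = "fold_safe"` (default) the GWAS ranking behind a
#' `top_gwas` panel is re-run inside each training fold; `"whole_data"` ranks
#' once on all individuals, mimicking a common but leaky practice.
#'
#' @param genotypes complete [geno_matrix()]
#' @param phenotypes data.frame with `duration_h` and `batch` (as from
#'   [simulate_phenotype()]); batch enters the fixed effects
#' @param models character subset of `c("GBLUP", "BayesB")`
#' @param panels list of [panel_spec()] objects
#' @param folds a [make_folds()] plan
#' @param leakage_mode `"fold_safe"` or `"whole_data"`
#' @param chain chain controls for BayesB (see [chain_profile()])
#' @param pi BayesB prior null probability
#' @param keep_predictions if `TRUE`, out-of-fold GEBVs are returned per
#'   (model, panel, repeat) for auditing (e.g. the no-leakage invariant)
#' @return object of class `cv_result`: `cells` (tidy data.frame: model,
#'   panel_mode, panel_size, repeat, fold, accuracy; bias attached per
#'   repeat), `aggregate` (mean and SD of accuracy over repeats, mean bias)
#' @export
run_cv_experiment <- function(genotypes, phenotypes,
                              models = c("GBLUP"),
                              panels = list(panel_spec("all")),
                              folds, leakage_mode = c("fold_safe", "whole_data"),
                              chain = chain_profile("fast"), pi = 0.95,
                              keep_predictions = FALSE) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(folds, "fold_plan"))
  leakage_mode <- match.arg(leakage_mode)
  y <- phenotypes$duration_h
  n <- length(y)
  stopifnot(n == nrow(genotypes$dosage), n == folds$n)
  X <- stats::model.matrix(~ batch, data = phenotypes)
  d <- genotypes$dosage
  if (anyNA(d)) stop("CV requires complete genotypes; impute first")

  needs_gwas <- any(vapply(panels, function(p) p$mode == "top_gwas", TRUE))
  whole_scan <- NULL
  if (needs_gwas && leakage_mode == "whole_data") {
    grm_all <- grm_vanraden(genotypes)
    null_all <- fit_null_mlm(y, X, grm_all)
    whole_scan <- scan_association(genotypes, y, null_fit = null_all)
  }

  rows <- list(); bias_rows <- list(); errors <- list(); preds <- list()
  for (model in models) for (pn in panels) {
    psize <- if (pn$mode == "all") ncol(d) else pn$size
    for (r in seq_len(folds$repeats)) {
      fold_of <- folds$assignment[r, ]
      pred <- rep(NA_real_, n)
      for (f in seq_len(folds$k)) {
        test <- which(fold_of == f); train <- which(fold_of != f)
        res <- tryCatch({
          idx <- switch(pn$mode,
            all = seq_len(ncol(d)),
            random = build_panel(genotypes$map, pn),
            top_gwas = {
              scan <- if (leakage_mode == "whole_data") whole_scan else {
                gtr <- subset_geno(genotypes, i = train)
                grm_tr <- grm_vanraden(gtr)
                null_tr <- fit_null_mlm(y[train], X[train, , drop = FALSE], grm_tr)
                scan_association(gtr, y[train], null_fit = null_tr)
              }
              build_panel(scan, pn)
            })
          dsub <- d[, idx, drop = FALSE]
          if (model == "GBLUP") {
            gsub <- grm_vanraden(dsub)
            fit <- gblup_reml(y[train], X[train, , drop = FALSE],
                              gsub$matrix[train, train])
            sg2 <- fit$varcomp$sigma_g2; se2 <- fit$varcomp$sigma_e2
            Vtt <- sg2 * gsub$matrix[train, train]
            diag(Vtt) <- diag(Vtt) + se2 + 1e-6
            resid <- y[train] - fit$X %*% fit$beta
            a <- solve(Vtt, resid)
            as.vector(sg2 * gsub$matrix[test, train, drop = FALSE] %*% a)
          } else {
            bfit <- bayesb_gibbs(y[train], X[train, , drop = FALSE],
                                 dsub[train, , drop = FALSE], pi = pi,
                                 n_iter = chain$n_iter, burn_in = chain$burn_in,
                                 seed = folds$seed + 7919L * r + f)
            bayesb_predict(bfit, dsub[test, , drop = FALSE])
          }
        }, error = function(e) e)
        if (inherits(res, "error")) {
          errors[[length(errors) + 1]] <- data.frame(
            model = model, panel_mode = pn$mode, panel_size = psize,
            rep = r, fold = f, message = conditionMessage(res))
          next
        }
        pred[test] <- res
        # zero-variance predictions (boundary fit: no usable signal in the
        # panel) leave the fold's accuracy undefined; record NA, keep going
        acc <- tryCatch(accuracy(y[test], res), error = function(e) NA_real_)
        rows[[length(rows) + 1]] <- data.frame(
          model = model, panel_mode = pn$mode, panel_size = psize,
          rep = r, fold = f, accuracy = acc)
      }
      if (keep_predictions)
        preds[[paste(model, pn$mode, psize, r, sep = "|")]] <- pred
      ok <- !is.na(pred)
      if (sum(ok) >= 3 && stats::var(pred[ok]) > 0)
        bias_rows[[length(bias_rows) + 1]] <- data.frame(
          model = model, panel_mode = pn$mode, panel_size = psize,
          rep = r, bias = bias(y[ok], pred[ok]))
    }
  }
  cells <- do.call(rbind, rows)
  biases <- if (length(bias_rows)) do.call(rbind, bias_rows) else NULL
  agg <- stats::aggregate(accuracy ~ model + panel_mode + panel_size,
                          data = cells, FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  names(agg)[names(agg) == "accuracy"] <- "mean_accuracy"
  agg$sd_accuracy <- stats::aggregate(accuracy ~ model + panel_mode + panel_size,
                                      data = cells, FUN = stats::sd,
                                      na.rm = TRUE,
                                      na.action = stats::na.pass)$accuracy
  if (!is.null(biases)) {
    bm <- stats::aggregate(bias ~ model + panel_mode + panel_size,
                           data = biases, FUN = mean)
    agg <- merge(agg, bm, all.x = TRUE)
  }
  structure(list(cells = cells, biases = biases, aggregate = agg,
                 leakage_mode = leakage_mode,
                 predictions = if (keep_predictions) preds,
                 errors = if (length(errors)) do.call(rbind, errors)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s):\n", x$leakage_mode))
  print(x$aggregate, row.names = FALSE)
  if (!is.null(x$errors)) cat(nrow(x$errors), "cell failures recorded\n")
  invisible(x)
}

#' Write CV grid results as tidy CSVs
#'
#' @param cv a [run_cv_experiment()] result
#' @param prefix path prefix: `<prefix>_cells.csv` and `<prefix>_aggregate.csv`
#' @export
write_cv_csv <- function(cv, prefix) {
  data.table::fwrite(cv$cells, paste0(prefix, "_cells.csv"))
  data.table::fwrite(cv$aggregate, paste0(prefix, "_aggregate.csv"))
  invisible(prefix)
}
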