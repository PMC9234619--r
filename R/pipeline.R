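# Config-driven end-to-end orchestration:
# simulate -> QC -> structure -> GWAS -> prediction -> CV grid.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the package defaults; override
#' entries via `...` (top-level sections only) or load from JSON with
#' [read_pipeline_config()]. The `"fast"` profile scales the simulation and
#' chain lengths for smoke tests; `"paper"` uses the study-scale settings.
#'
#' @param profile `"fast"` or `"paper"`
#' @param ... named top-level overrides (e.g. `simulate = list(...)`)
#' @return a `pipeline_config` list
#' @export
default_config <- function(profile = c("fast", "paper"), ...) {
  profile <- match.arg(profile)
  fast <- profile == "fast"
  cfg <- list(
    profile = profile,
    seed = 1L,
    simulate = list(
      n_founders = if (fast) 80 else 400,
      n_offspring = if (fast) 200 else 1120,
      m = if (fast) 1000 else 64788,
      n_chrom = 18, chrom_length = 5e7,
      n_qtl = if (fast) 50 else 200,
      h2_target = 0.40, missing_rate = 0.008,
      maf_range = c(0.05, 0.5), ld_rho = 0.9, n_batches = 4),
    qc = list(maf_min = 0.05, snp_call_min = 0.95, ind_call_min = 0.80),
    impute = list(mode = "mean"),
    structure = list(k = 10, n_pcs_gwas = 3, ridge = 1e-6),
    gwas = list(alpha = 0.05, suggestive = 1e-5),
    predict = list(models = c("GBLUP", "BayesB"), pi = 0.95,
                   chain_profile = if (fast) "fast" else "paper"),
    cv = list(k = 5, repeats = if (fast) 2 else 10,
              panel_sizes = if (fast) c(100, 500) else
                c(500, 1000, 5000, 10000, 20000, 40000),
              panel_modes = c("top_gwas", "random"),
              include_all_panel = TRUE,
              leakage_mode = "fold_safe"))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' The file may specify any subset of sections; unspecified values take the
#' profile defaults. Validation happens in [validate_config()] before any
#' compute.
#'
#' @param path JSON file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  profile <- if (!is.null(js$profile)) js$profile else "fast"
  args <- js[setdiff(names(js), "profile")]
  do.call(default_config, c(list(profile = profile), args))
}

#' Validate a pipeline configuration
#'
#' Structural schema check run before any compute; throws on the first
#' violation.
#'
#' @param cfg a `pipeline_config`
#' @return `cfg`, invisibly, if valid
#' @export
validate_config <- function(cfg) {
  need <- c("profile", "seed", "simulate", "qc", "impute", "structure",
            "gwas", "predict", "cv")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) stop("config missing sections: ",
                            paste(missing, collapse = ", "))
  s <- cfg$simulate
  if (s$n_founders < 2) stop("simulate.n_founders must be >= 2")
  if (s$n_offspring < 10) stop("simulate.n_offspring must be >= 10")
  if (s$h2_target < 0 || s$h2_target > 1) stop("simulate.h2_target in [0,1]")
  if (s$missing_rate < 0 || s$missing_rate >= 1) stop("simulate.missing_rate in [0,1)")
  for (v in unlist(cfg$qc)) if (v < 0 || v > 1) stop("qc thresholds in [0,1]")
  if (!cfg$impute$mode %in% c("mean", "sample")) stop("impute.mode invalid")
  if (cfg$cv$k < 2) stop("cv.k must be >= 2")
  if (cfg$cv$repeats < 1) stop("cv.repeats must be >= 1")
  if (!cfg$cv$leakage_mode %in% c("fold_safe", "whole_data"))
    stop("cv.leakage_mode invalid")
  if (!all(cfg$predict$models %in% c("GBLUP", "BayesB")))
    stop("predict.models must be within GBLUP/BayesB")
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Stages run in order (simulate, qc, impute, structure, gwas, predict, cv);
#' every stage derives its seed from the global seed and the stage name, all
#' artifacts are written under `out_dir`, and an md5 provenance manifest is
#' emitted so identical configs reproduce identical hashes.
#'
#' @param cfg a `pipeline_config` (validated before any compute)
#' @param out_dir output directory (created if absent)
#' @param stages subset of stages to run (later stages need earlier outputs
#'   in memory, so this mainly supports truncating the tail)
#' @param quiet suppress progress lines
#' @return list with all stage outputs plus `manifest`
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("absrun"),
                         stages = c("simulate", "qc", "impute", "structure",
                                    "gwas", "predict", "cv"),
                         quiet = FALSE) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, c("simulate", "impute", "cv", "bayesb"))
  say <- function(stage, fmt, ...) if (!quiet)
    message(sprintf("[%s seed=%d] %s", stage, cfg$seed, sprintf(fmt, ...)))
  t0 <- proc.time()[["elapsed"]]
  out <- list(config = cfg)
  files <- character(0)
  emit <- function(path) files <<- c(files, path)

  run_stage <- function(stage, expr) {
    t <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    say(stage, "done in %.1fs", proc.time()[["elapsed"]] - t)
    res
  }

  if ("simulate" %in% stages) {
    out$sim <- run_stage("simulate", {
      s <- cfg$simulate
      simulate_population(n_founders = s$n_founders,
                          n_offspring = s$n_offspring, m = s$m,
                          n_chrom = s$n_chrom, chrom_length = s$chrom_length,
                          n_qtl = s$n_qtl, h2_target = s$h2_target,
                          missing_rate = s$missing_rate,
                          maf_range = s$maf_range, ld_rho = s$ld_rho,
                          n_batches = s$n_batches,
                          seed = seeds[["simulate"]])
    })
    emit(write_phenotype_csv(out$sim$phenotypes,
                             file.path(out_dir, "phenotypes.csv")))
    data.table::fwrite(out$sim$pedigree, file.path(out_dir, "pedigree.csv"))
    emit(file.path(out_dir, "pedigree.csv"))
    att <- attachment_summary(out$sim$phenotypes$duration_h)
    data.table::fwrite(att$bins, file.path(out_dir, "attachment_curve.csv"))
    emit(file.path(out_dir, "attachment_curve.csv"))
  }
  if ("qc" %in% stages) {
    out$qc <- run_stage("qc", {
      apply_qc(out$sim$genotypes,
               qc_thresholds(cfg$qc$maf_min, cfg$qc$snp_call_min,
                             cfg$qc$ind_call_min))
    })
    say("qc", "%d -> %d SNPs, %d -> %d individuals",
        out$qc$report$n_snps_in, out$qc$report$n_snps_out,
        out$qc$report$n_ind_in, out$qc$report$n_ind_out)
    emit(qc_report_json(out$qc$report, file.path(out_dir, "qc_report.json")))
  }
  if ("impute" %in% stages) {
    out$geno <- run_stage("impute", {
      impute_naive(out$qc$genotypes, mode = cfg$impute$mode,
                   seed = seeds[["impute"]])
    })
    keep <- match(out$qc$genotypes$ids, out$sim$phenotypes$id)
    out$pheno <- out$sim$phenotypes[keep, , drop = FALSE]
  }
  if ("structure" %in% stages) {
    out$grm <- run_stage("structure-grm", grm_vanraden(out$geno))
    out$structure <- run_stage("structure-pca",
                               pca_structure(out$grm, k = cfg$structure$k))
    emit(write_grm_csv(out$grm, file.path(out_dir, "grm.csv")))
    pcs <- as.data.frame(out$structure$scores)
    data.table::fwrite(cbind(id = rownames(out$structure$scores), pcs),
                       file.path(out_dir, "pcs.csv"))
    emit(file.path(out_dir, "pcs.csv"))
  }
  if ("gwas" %in% stages) {
    out$gwas <- run_stage("gwas", {
      y <- out$pheno$duration_h
      npc <- min(cfg$structure$n_pcs_gwas, ncol(out$structure$scores))
      X <- cbind(stats::model.matrix(~ batch, data = out$pheno),
                 out$structure$scores[, seq_len(npc), drop = FALSE])
      grm_r <- grm_ridge(out$grm, cfg$structure$ridge)
      null_fit <- fit_null_mlm(y, X, grm_r, ridge = 0)
      scan <- scan_association(out$geno, y, null_fit = null_fit)
      thr <- compute_thresholds(nrow(scan), cfg$gwas$alpha, cfg$gwas$suggestive)
      cls <- classify_snps(scan, thr)
      list(scan = scan, thresholds = thr, classified = cls,
           null_fit = null_fit)
    })
    say("gwas", "genome-wide %d, suggestive %d (thresholds %.3g / %.3g)",
        out$gwas$classified$counts["genome_wide"],
        out$gwas$classified$counts["suggestive"],
        out$gwas$thresholds$genome_wide_p, out$gwas$thresholds$suggestive_p)
    tab <- out$gwas$classified$table
    data.table::fwrite(tab, file.path(out_dir, "gwas_results.tsv"), sep = "\t")
    emit(file.path(out_dir, "gwas_results.tsv"))
    mq <- export_manhattan_qq(out$gwas$scan)
    data.table::fwrite(mq$manhattan, file.path(out_dir, "manhattan.csv"))
    data.table::fwrite(mq$qq, file.path(out_dir, "qq.csv"))
    emit(file.path(out_dir, "manhattan.csv")); emit(file.path(out_dir, "qq.csv"))
  }
  if ("predict" %in% stages) {
    out$predict <- run_stage("predict", {
      y <- out$pheno$duration_h
      X <- stats::model.matrix(~ batch, data = out$pheno)
      res <- list()
      if ("GBLUP" %in% cfg$predict$models)
        res$GBLUP <- gblup_reml(y, X, out$grm, ridge = cfg$structure$ridge)
      if ("BayesB" %in% cfg$predict$models) {
        ch <- chain_profile(cfg$predict$chain_profile)
        res$BayesB <- bayesb_gibbs(y, X, out$geno$dosage,
                                   pi = cfg$predict$pi,
                                   n_iter = ch$n_iter, burn_in = ch$burn_in,
                                   seed = seeds[["bayesb"]])
      }
      res
    })
    vc <- do.call(rbind, lapply(names(out$predict), function(mn) {
      v <- out$predict[[mn]]$varcomp
      data.frame(model = mn, sigma_g2 = v$sigma_g2, sigma_e2 = v$sigma_e2,
                 sigma_p2 = v$sigma_p2, h2 = v$h2)
    }))
    data.table::fwrite(vc, file.path(out_dir, "variance_components.csv"))
    emit(file.path(out_dir, "variance_components.csv"))
    gebv <- do.call(rbind, lapply(names(out$predict), function(mn)
      data.frame(id = out$pheno$id, gebv = out$predict[[mn]]$gebv,
                 model = mn, panel = "all")))
    data.table::fwrite(gebv, file.path(out_dir, "gebv.csv"))
    emit(file.path(out_dir, "gebv.csv"))
  }
  if ("cv" %in% stages) {
    out$cv <- run_stage("cv", {
      n <- nrow(out$geno$dosage)
      folds <- make_folds(n, cfg$cv$k, cfg$cv$repeats, seed = seeds[["cv"]])
      sizes <- cfg$cv$panel_sizes[cfg$cv$panel_sizes <= ncol(out$geno$dosage)]
      panels <- list()
      for (sz in sizes) for (md in cfg$cv$panel_modes)
        panels[[length(panels) + 1]] <- panel_spec(md, sz, seed = seeds[["cv"]] + sz)
      if (isTRUE(cfg$cv$include_all_panel))
        panels[[length(panels) + 1]] <- panel_spec("all")
      run_cv_experiment(out$geno, out$pheno, models = cfg$predict$models,
                        panels = panels, folds = folds,
                        leakage_mode = cfg$cv$leakage_mode,
                        chain = chain_profile(cfg$predict$chain_profile),
                        pi = cfg$predict$pi)
    })
    write_cv_csv(out$cv, file.path(out_dir, "cv"))
    emit(file.path(out_dir, "cv_cells.csv"))
    emit(file.path(out_dir, "cv_aggregate.csv"))
  }

  manifest <- list(
    package = "abaloneGS",
    seed = cfg$seed, profile = cfg$profile, stages = stages,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
    files = lapply(stats::setNames(nm = basename(files)), function(b) {
      unname(tools::md5sum(file.path(out_dir, b)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  out$out_dir <- out_dir
  invisible(out)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `qc`, `structure`, `gwas`, `predict`, `cv`,
#' `run-all`; each runs the pipeline up to and including that stage.
#' Flags: `--config <json>`, `--seed <int>`, `--out <dir>`,
#' `--profile {fast,paper}`. Returns 0 on success, nonzero (with the failing
#' stage named on stderr) otherwise.
#'
#' @param argv character vector of CLI arguments (default: the process args)
#' @return exit status, invisibly
#' @export
gs_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  stage_map <- list(simulate = "simulate",
                    qc = c("simulate", "qc"),
                    structure = c("simulate", "qc", "impute", "structure"),
                    gwas = c("simulate", "qc", "impute", "structure", "gwas"),
                    predict = c("simulate", "qc", "impute", "structure",
                                "gwas", "predict"),
                    cv = c("simulate", "qc", "impute", "structure", "gwas",
                           "predict", "cv"),
                    "run-all" = c("simulate", "qc", "impute", "structure",
                                  "gwas", "predict", "cv"))
  usage <- paste0("usage: abaloneGS <", paste(names(stage_map), collapse = "|"),
                  "> [--config path] [--seed int] [--out dir] [--profile fast|paper]")
  if (length(argv) < 1 || !argv[1] %in% names(stage_map)) {
    message(usage); return(invisible(2L))
  }
  sub <- argv[1]; argv <- argv[-1]
  opt <- list(config = NULL, seed = NULL, out = NULL, profile = NULL)
  i <- 1
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opt) || i == length(argv)) {
      message("unknown or valueless flag: ", argv[i]); return(invisible(2L))
    }
    opt[[key]] <- argv[i + 1]; i <- i + 2
  }
  status <- tryCatch({
    cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
           else default_config(if (is.null(opt$profile)) "fast" else opt$profile)
    if (!is.null(opt$profile)) cfg$profile <- opt$profile
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    out_dir <- if (is.null(opt$out)) file.path(getwd(), "abaloneGS_out") else opt$out
    run_pipeline(cfg, out_dir = out_dir, stages = stage_map[[sub]])
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
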