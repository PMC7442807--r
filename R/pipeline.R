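# Benchmark orchestration: simulate replicates, fit every requested
# predictor on the training half, predict the independent test half,
# evaluate, and aggregate replicate summaries.

#' Configure a prediction benchmark
#'
#' Scenario parameters may be vectors (`k`, `effect_dist`, `neg_shape`,
#' `h2`); the benchmark runs their crossing. Defaults mirror a two-cohort
#' array study scaled to a desk-feasible marker panel: 3685 training and
#' 3048 test samples, 20000 variants, 20 replicates.
#'
#' @param n_train,n_test sample counts for the training and test halves.
#' @param m variant count of the simulated panel.
#' @param k causal-variant count(s).
#' @param effect_dist effect-size distribution(s): `"normal"`,
#'   `"laplace"`, `"neg"`.
#' @param neg_shape gamma shape(s) for the NEG family (used only when
#'   `effect_dist` includes `"neg"`).
#' @param h2 nominal heritability/ies in (0, 1).
#' @param maf_low,maf_high minor-allele-frequency bounds of the panel.
#' @param r2_max linkage-equilibrium bound for the causal set.
#' @param n_reps replicates per scenario (default 20).
#' @param methods predictors to run, a subset of `"stmgp"`, `"prs"`,
#'   `"gblup"`, `"sblup"`, `"ridge"`.
#' @param covariate_mode how test accuracy is computed: `"none"` (plain
#'   correlation), `"partial"`, or `"regress_out"` (see
#'   [covariate_mode_apply()]).
#' @param use_covariates simulate age/sex covariates and inject their
#'   effects into the phenotype.
#' @param covariate_coef effect sizes for injected covariates.
#' @param sblup_max_variants cap on the SBLUP joint-solve candidate set
#'   (top clumped variants by P; the solve is cubic in this count).
#' @param seed root seed; every replicate derives named substreams from it.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(n_train = 3685, n_test = 3048, m = 20000,
                             k = 100, effect_dist = "laplace",
                             neg_shape = 3, h2 = 0.10,
                             maf_low = 0.01, maf_high = 0.5,
                             r2_max = 0.05, n_reps = 20,
                             methods = c("stmgp", "prs", "gblup", "sblup",
                                         "ridge"),
                             covariate_mode = c("none", "partial",
                                                "regress_out"),
                             use_covariates = FALSE,
                             covariate_coef = c(age = 0.02, sex = 0.25),
                             sblup_max_variants = 2000,
                             seed = 1L) {
  covariate_mode <- match.arg(covariate_mode)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(n_train >= 10, n_test >= 10, m >= 10, n_reps >= 1)
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must be in (0, 1)", call. = FALSE)
  if (any(k > m)) stop("k exceeds m", call. = FALSE)
  scen <- expand.grid(k = k, effect_dist = effect_dist,
                      neg_shape = neg_shape, h2 = h2,
                      stringsAsFactors = FALSE)
  # the NEG shape only matters for the NEG family
  scen <- unique(within(scen, neg_shape[effect_dist != "neg"] <- NA))
  mem_gb <- (n_train + n_test) * m * 8 / 2^30
  structure(list(n_train = n_train, n_test = n_test, m = m,
                 scenarios = scen, maf_low = maf_low, maf_high = maf_high,
                 r2_max = r2_max, n_reps = n_reps, methods = methods,
                 covariate_mode = covariate_mode,
                 use_covariates = use_covariates,
                 covariate_coef = covariate_coef,
                 sblup_max_variants = sblup_max_variants,
                 seed = as.integer(seed),
                 est_memory_gb = mem_gb,
                 feasible = mem_gb < 6),
            class = "benchmark_config")
}

#' @export
print.benchmark_config <- function(x, ...) {
  cat("<benchmark_config> ", nrow(x$scenarios), " scenario(s) x ",
      x$n_reps, " replicates; n = ", x$n_train, "+", x$n_test,
      ", m = ", x$m, "\n  methods: ",
      paste(x$methods, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate a prediction under a covariate-handling mode
#'
#' Routes to the plain predictive correlation (`"none"`), the partial
#' correlation controlling for the covariates (`"partial"`), or the
#' correlation of the prediction with the covariate-regression residuals of
#' the phenotype (`"regress_out"`). All three coincide when `C` is empty.
#'
#' @param mode one of `"none"`, `"partial"`, `"regress_out"`.
#' @param y observed phenotype.
#' @param C covariates (may be `NULL`).
#' @param pred predicted values.
#' @return List with `r`, `p_value`, `n`.
#' @export
covariate_mode_apply <- function(mode, y, C, pred) {
  if (!mode %in% c("none", "partial", "regress_out"))
    stop("unknown covariate mode: ", mode, call. = FALSE)
  if (is.null(C) || mode == "none") return(pcc(pred, y))
  if (mode == "partial") return(partial_correlation(pred, y, C))
  pcc(pred, .residualize(y, C))
}

# one replicate of one scenario; returns a data.frame of per-method rows
.run_replicate <- function(cfg, scen, si, ri) {
  n_tr <- cfg$n_train
  n_te <- cfg$n_test
  m <- cfg$m
  tag <- si * 1000L + ri
  # shared per-variant frequencies, then independent train/test blocks
  set.seed(.substream_seed(cfg$seed, "maf", tag))
  p <- runif(m, cfg$maf_low, cfg$maf_high)
  set.seed(.substream_seed(cfg$seed, "genotypes", tag))
  Xtr <- .simulate_dosages(n_tr, p)
  Xte <- .simulate_dosages(n_te, p)

  set.seed(.substream_seed(cfg$seed, "causal", tag))
  causal <- .select_causal_2(Xtr, Xte, scen$k, cfg$r2_max)
  b <- sample_effects(scen$k, scen$effect_dist,
                      neg_shape = if (is.na(scen$neg_shape)) 3
                                  else scen$neg_shape,
                      seed = .substream_seed(cfg$seed, "effects", tag))
  # genetic score standardized with combined-sample frequencies
  Xc <- rbind(Xtr[, causal, drop = FALSE], Xte[, causal, drop = FALSE])
  pc <- colMeans(Xc) / 2
  Wc <- standardize_genotypes(Xc, freq = pc)
  phen <- simulate_phenotype(Wc, b, scen$h2,
                             seed = .substream_seed(cfg$seed, "residuals",
                                                    tag))
  y_tr <- phen$y[seq_len(n_tr)]
  y_te <- phen$y[n_tr + seq_len(n_te)]

  C_tr <- C_te <- NULL
  if (cfg$use_covariates) {
    cov_all <- simulate_covariates(n_tr + n_te,
                                   seed = .substream_seed(cfg$seed,
                                                          "covariates",
                                                          tag))
    y_all <- inject_covariate_effect(phen$y, cov_all, cfg$covariate_coef)
    y_tr <- y_all[seq_len(n_tr)]
    y_te <- y_all[n_tr + seq_len(n_te)]
    C_tr <- cov_all[seq_len(n_tr), , drop = FALSE]
    C_te <- cov_all[n_tr + seq_len(n_te), , drop = FALSE]
  }

  gwas <- gwas_scan(Xtr, y_tr, C_tr)
  freq_tr <- allele_freq(Xtr)
  rows <- list()
  # a constant prediction is a model asserting no signal: it scores r = 0,
  # P = 1 (counted as a nonsignificant replicate, never dropped)
  eval_pred <- function(y, C, pred) {
    if (sd(pred) == 0) return(list(r = 0, p_value = 1))
    covariate_mode_apply(cfg$covariate_mode, y, C, pred)
  }
  add_row <- function(method, pred_tr, pred_te) {
    ev_te <- tryCatch(eval_pred(y_te, C_te, pred_te),
                      error = function(e) list(r = NA_real_,
                                               p_value = NA_real_))
    ev_tr <- tryCatch(eval_pred(y_tr, C_tr, pred_tr),
                      error = function(e) list(r = NA_real_,
                                               p_value = NA_real_))
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario = si, rep = ri, method = method,
      k = scen$k, effect_dist = scen$effect_dist,
      neg_shape = scen$neg_shape, h2 = scen$h2,
      r_train = ev_tr$r, r_test = ev_te$r, p_test = ev_te$p_value,
      realized_h2 = phen$realized_h2,
      error = NA_character_, stringsAsFactors = FALSE)
  }
  add_failure <- function(method, msg) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario = si, rep = ri, method = method,
      k = scen$k, effect_dist = scen$effect_dist,
      neg_shape = scen$neg_shape, h2 = scen$h2,
      r_train = NA_real_, r_test = NA_real_, p_test = NA_real_,
      realized_h2 = phen$realized_h2,
      error = msg, stringsAsFactors = FALSE)
  }

  geno_tr <- NULL  # built lazily for methods needing metadata
  get_geno_tr <- function() {
    if (is.null(geno_tr))
      geno_tr <<- genotype_matrix(Xtr, validate = FALSE)
    geno_tr
  }

  for (method in cfg$methods) {
    res <- tryCatch({
      switch(method,
        stmgp = {
          fit <- stmgp_fit(Xtr, y_tr, C_tr, gwas = gwas)
          list(tr = predict(fit, Xtr, C_tr), te = predict(fit, Xte, C_te))
        },
        prs = {
          fit <- prs_fit(gwas, get_geno_tr(), y_tr, C_tr)
          list(tr = predict(fit, Xtr), te = predict(fit, Xte))
        },
        gblup = {
          W_tr <- standardize_genotypes(Xtr, freq = freq_tr)
          grm_tr <- make_grm(W_tr)
          vc <- greml(y_tr, grm_tr, C_tr)
          W_te <- standardize_genotypes(Xte, freq = freq_tr)
          grm_te_tr <- tcrossprod(W_te, W_tr) / ncol(W_tr)
          grm_tr_tr <- grm_tr
          list(tr = gblup_predict(vc, grm_tr, grm_tr, y_tr, C_tr, C_tr),
               te = gblup_predict(vc, grm_tr, grm_te_tr, y_tr, C_tr, C_te))
        },
        sblup = {
          cl <- clump_variants(gwas, get_geno_tr())
          cl <- cl[order(gwas$p[cl])]
          cl <- sort(head(cl, cfg$sblup_max_variants))
          W_tr <- standardize_genotypes(Xtr[, cl, drop = FALSE],
                                        freq = freq_tr[cl])
          R <- crossprod(W_tr) / (n_tr - 1)
          vc_h2 <- {
            g0 <- greml(y_tr, make_grm(W_tr), C_tr)
            min(max(g0$h2, 0.01), 0.99)
          }
          bj <- sblup_coefficients(gwas$beta[cl], R, n_tr, vc_h2, m = m)
          W_te <- standardize_genotypes(Xte[, cl, drop = FALSE],
                                        freq = freq_tr[cl])
          list(tr = as.vector(W_tr %*% bj), te = as.vector(W_te %*% bj))
        },
        ridge = {
          cl <- clump_variants(gwas, get_geno_tr())
          fit <- ridge_clumped(Xtr[, cl, drop = FALSE], y_tr, C_tr)
          list(tr = predict(fit, Xtr[, cl, drop = FALSE], C_tr),
               te = predict(fit, Xte[, cl, drop = FALSE], C_te))
        })
    }, error = function(e) e)
    if (inherits(res, "error")) add_failure(method, conditionMessage(res))
    else add_row(method, res$tr, res$te)
  }
  do.call(rbind, rows)
}

# causal selection across the combined sample held as two blocks
.select_causal_2 <- function(Xtr, Xte, k, r2_max) {
  m <- ncol(Xtr)
  n <- nrow(Xtr) + nrow(Xte)
  ord <- sample.int(m)
  accepted <- integer(0)
  Z <- matrix(0, n, k)
  for (j in ord) {
    x <- c(Xtr[, j], Xte[, j])
    s <- sd(x)
    if (!is.finite(s) || s == 0) next
    z <- (x - mean(x)) / s
    if (length(accepted)) {
      r <- crossprod(Z[, seq_along(accepted), drop = FALSE], z) / (n - 1)
      if (max(r^2) >= r2_max) next
    }
    Z[, length(accepted) + 1L] <- z
    accepted <- c(accepted, j)
    if (length(accepted) == k) return(accepted)
  }
  stop("could not find ", k, " variants at r2 < ", r2_max, call. = FALSE)
}

#' Run a prediction benchmark
#'
#' For every scenario and replicate: simulate genotypes and a phenotype
#' across training and test samples jointly, fit each requested method on
#' the training half only (training-frequency standardization throughout),
#' predict the test half, and evaluate. Per-method failures are recorded
#' per replicate and the run continues. Fully reproducible from the root
#' seed; with `output_dir` set, completed replicates are written as JSON
#' and skipped on re-run (resume).
#'
#' @param config a [benchmark_config()].
#' @param output_dir optional directory for per-replicate JSON results and
#'   the summary TSV.
#' @param verbose print progress lines.
#' @return An object of class `benchmark_result`: `summary` (one row per
#'   scenario x method: mean/SD of test correlations, power, mean
#'   overfitting gap), `replicates` (all per-replicate rows), `config`.
#' @export
run_benchmark <- function(config, output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  if (!is.null(output_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  reps <- list()
  for (si in seq_len(nrow(config$scenarios))) {
    scen <- config$scenarios[si, , drop = FALSE]
    for (ri in seq_len(config$n_reps)) {
      cache <- if (!is.null(output_dir))
        file.path(output_dir, sprintf("s%02d_r%02d.json", si, ri))
      if (!is.null(cache) && file.exists(cache)) {
        rows <- as.data.frame(jsonlite::read_json(cache,
                                                  simplifyVector = TRUE))
      } else {
        rows <- .run_replicate(config, scen, si, ri)
        if (!is.null(cache))
          jsonlite::write_json(rows, cache, auto_unbox = FALSE, digits = NA,
                               na = "null")
      }
      if (verbose)
        message(sprintf("scenario %d rep %d: %s", si, ri,
                        paste(sprintf("%s r=%.3f", rows$method,
                                      rows$r_test), collapse = "  ")))
      reps[[length(reps) + 1L]] <- rows
    }
  }
  replicates <- do.call(rbind, reps)
  key <- interaction(replicates$scenario, replicates$method, drop = TRUE)
  summ <- do.call(rbind, lapply(split(replicates, key), function(d) {
    ok <- !is.na(d$r_test)
    ps <- if (any(ok)) power_summary(d$r_test[ok], d$p_test[ok])
          else list(mean_r = NA_real_, sd_r = NA_real_, power = NA_real_,
                    n_reps = 0L)
    data.frame(scenario = d$scenario[1], method = d$method[1],
               k = d$k[1], effect_dist = d$effect_dist[1],
               neg_shape = d$neg_shape[1], h2 = d$h2[1],
               mean_pcc = ps$mean_r, sd_pcc = ps$sd_r, power = ps$power,
               mean_train_r = mean(d$r_train[ok]),
               mean_overfit_gap = mean(d$r_train[ok] - d$r_test[ok]),
               n_reps = ps$n_reps, n_failed = sum(!ok),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  summ <- summ[order(summ$scenario, summ$method), , drop = FALSE]
  if (!is.null(output_dir))
    .write_tsv(summ, file.path(output_dir, "summary.tsv"))
  structure(list(summary = summ, replicates = replicates, config = config),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> ", nrow(x$config$scenarios), " scenario(s), ",
      x$config$n_reps, " replicates\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}
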