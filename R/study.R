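#' Run the simulation study
#'
#' For each simulation replicate: generate a genome with known truth
#' ([simulate_genome()]), apply the usability filter ([filter_genes()]),
#' run the requested methods, call significance at estimated FDR `alpha`
#' (Bayesian FDR for the model-selection variants, Storey q-values for the
#' baselines), and score the calls against the truth sets — gene-level ASE
#' is true for genes generated from models 2 or 4, SNP-level variation for
#' models 3 or 4, the simultaneous hypothesis for model 4 only.
#'
#' @param cfg a [sim_config()].
#' @param methods subset of `"blmrm"`, `"blmrm_pure_laplace"`, `"glmm"`,
#'   `"binomial"`, `"anova"`.
#' @param alpha FDR level.
#' @param fpr_max right end of the partial-ROC window.
#' @param control a [blmrm_control()] list.
#' @param verbose print per-replicate progress.
#' @return list of class `"blmrm_study"` with elements `per_rep` (one row
#'   per replicate, method and hypothesis: true FDR, TPr, partial AUC),
#'   `summary` (means and SDs across replicates), `hyperparameters` (one
#'   row per replicate of estimated values, when a model-selection method
#'   ran), `filter_reports`, and `config`.
#' @export
run_study <- function(cfg, methods = c("blmrm", "glmm", "binomial"),
                      alpha = 0.05, fpr_max = 0.3,
                      control = blmrm_control(), verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("blmrm", "blmrm_pure_laplace", "glmm",
                                   "binomial", "anova"))
  per_rep <- list()
  hp_rows <- list()
  reports <- list()

  for (r in seq_len(cfg$n_sims)) {
    if (verbose) message("simulation replicate ", r, "/", cfg$n_sims)
    sim <- simulate_genome(cfg, r)
    fg <- filter_genes(sim$dataset)
    ds <- fg$dataset
    reports[[r]] <- fg$report
    truth <- sim$truth[match(names(ds$genes), sim$truth$gene), ]
    truth_sets <- list(gene = truth$true_model %in% c(2L, 4L),
                       snp = truth$true_model %in% c(3L, 4L),
                       gene_snp = truth$true_model == 4L)

    needs_ms <- any(c("blmrm", "blmrm_pure_laplace") %in% methods)
    needs_glmm <- "glmm" %in% methods

    # shared raw-count fits: models 1..4 for the GLMM baseline, model 4
    # also feeds the empirical-Bayes plug-ins
    raw_fits <- NULL
    if (needs_glmm || needs_ms) {
      wanted <- if (needs_glmm) 1:4 else 4L
      raw_fits <- lapply(ds$genes, function(g) {
        cells <- gene_cells(g)
        lapply(stats::setNames(wanted, wanted), function(m)
          fit_ml_cells(cells, m, control, g$gene_id))
      })
    }

    hp <- NULL
    if (needs_ms) {
      hp <- estimate_hyperparameters(ds, fdr_level = alpha,
                                     control = control)
      hp_rows[[length(hp_rows) + 1L]] <-
        data.frame(rep = r, mu = hp$mu, sigma2 = hp$sigma2, a_s = hp$a_s,
                   b_s = hp$b_s, a_r = hp$a_r, b_r = hp$b_r)
    }

    add_row <- function(method, hypothesis, calls, scores) {
      cc <- confusion_counts(calls, truth_sets[[hypothesis]])
      pauc <- tryCatch(roc_curve(scores, truth_sets[[hypothesis]],
                                 fpr_max)$pauc,
                       error = function(e) NA_real_)
      per_rep[[length(per_rep) + 1L]] <<-
        data.frame(rep = r, method = method, hypothesis = hypothesis,
                   fdr = cc$fdr, tpr = cc$tpr, pauc = pauc,
                   n_called = cc$TP + cc$FP, stringsAsFactors = FALSE)
    }

    for (method in methods) {
      if (method %in% c("blmrm", "blmrm_pure_laplace")) {
        fit4 <- lapply(raw_fits, `[[`, "4")
        res <- run_blmrm(ds, alpha = alpha, hp = hp,
                         laplace_only = method == "blmrm_pure_laplace",
                         control = control,
                         fits = if (method == "blmrm") fit4 else NULL)
        add_row(method, "gene", res$sig_gene, res$p_gene_ase)
        add_row(method, "snp", res$sig_snp, res$p_snp_var)
        add_row(method, "gene_snp", res$sig_both, res$p_both)
      } else if (method == "glmm") {
        p <- do.call(rbind, lapply(names(ds$genes), function(id) {
          gt <- glmm_tests(ds$genes[[id]], fits = raw_fits[[id]],
                           control = control)
          data.frame(p_gene = gt$p_gene, p_snp = gt$p_snp,
                     p_both = gt$p_both)
        }))
        for (h in c("gene", "snp", "gene_snp")) {
          pv <- switch(h, gene = p$p_gene, snp = p$p_snp,
                       gene_snp = p$p_both)
          q <- storey_qvalues(pv)
          add_row(method, h, q <= alpha, -pv)
        }
      } else {
        test_fun <- if (method == "binomial") binomial_ase_test else
          anova_ase_test
        pv <- vapply(ds$genes, function(g) as.numeric(test_fun(g)),
                     numeric(1))
        q <- storey_qvalues(pv)
        add_row(method, "gene", q <= alpha, -pv)
      }
    }
  }

  per_rep <- do.call(rbind, c(per_rep, list(make.row.names = FALSE)))
  structure(
    list(per_rep = per_rep, summary = summarize_perf(per_rep),
         hyperparameters = if (length(hp_rows))
           do.call(rbind, hp_rows) else NULL,
         filter_reports = reports, config = cfg),
    class = "blmrm_study")
}

#' @export
print.blmrm_study <- function(x, ...) {
  cat(sprintf("<blmrm_study> %d replicate(s), G=%d\n",
              x$config$n_sims, x$config$G))
  print(x$summary, digits = 3)
  invisible(x)
}
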