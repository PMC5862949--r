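# End-to-end pipeline: simulate (or load) -> contrasts -> set-activity
# profiles -> signature -> BCCP training with LOOCV -> cohort
# classification -> survival / chemo-response evaluation. Every numeric
# threshold is a config key; every filtering step is logged with input
# and surviving counts.

#' Default pipeline configuration
#'
#' A flat key/value list. Thresholds default to the standard analysis
#' values: raw p 0.05 with log2 fold-change cutoff 0.5 for significance,
#' divergence fold 1.5, signature fold 1.3 in >= 3 experiments, minimum
#' set size 5, and posterior cutoffs 0.3/0.7 for the tri-state call.
#'
#' @return named list of configuration defaults
#' @export
default_config <- function() {
  list(
    seed = 1,
    p_cut = 0.05,
    fc_cut = 0.5,
    divergent_fold = 1.5,
    signature_fold = 1.3,
    min_experiments = 3,
    min_set_size = 5,
    low_cut = 0.3,
    high_cut = 0.7,
    # synthetic stage: a panel of two-condition triplicated experiments
    n_experiments = 4,
    n_genes = 4000,
    n_sets = 100,
    set_size = 50,
    n_planted = 5,
    planted_delta = 0.5,
    noise_sd = 0.5,
    # synthetic cohort
    n_patients = 285,
    prevalence = 0.5,
    delta_sig = 1,
    baseline_hazard = 0.015,
    hazard_ratio = 3,
    censoring_rate = 0.3,
    p_resistant_high = 0.15,
    p_resistant_low = 0.02
  )
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  required <- names(default_config())
  missing <- setdiff(required, names(config))
  if (length(missing) > 0)
    stop("config missing required key(s): ", paste(missing, collapse = ", "))
  config
}

#' Run the full synthetic-to-evaluation pipeline
#'
#' Simulates a panel of nc886-high/low experiments (the last one a
#' knockdown, orientation -1) with MIR sets planted in the treated
#' condition, plus a patient cohort; then runs contrasts, MIR/TFT
#' activity profiles, oriented MIR ranking, signature derivation, BCCP
#' training with LOOCV, cohort classification, and survival / chemo /
#' ROC evaluation. All stage outputs are written under `outdir` and a
#' log records every threshold and filtering step.
#'
#' @param config a config list (see [default_config()]) or a YAML/JSON
#'   path; all keys are required
#' @param outdir output directory, created if absent
#' @return invisibly, a named list of the files written
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  cfg <- .load_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  logf <- function(...) writeLines(sprintf(...), log_con)
  files <- c(log = log_path)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  logf("config:")
  for (k in names(cfg)) logf("  %s = %s", k, format(cfg[[k]]))

  ## stage: simulate -------------------------------------------------
  sim <- run_stage("simulate", {
    mir <- random_collection(cfg$n_sets, cfg$set_size, cfg$n_genes,
                             name = "MIR", seed = cfg$seed + 101)
    tft <- random_collection(cfg$n_sets, cfg$set_size, cfg$n_genes,
                             name = "TFT", seed = cfg$seed + 102)
    planted_sets <- names(mir$sets)[seq_len(cfg$n_planted)]
    experiments <- lapply(seq_len(cfg$n_experiments), function(k) {
      kd <- k == cfg$n_experiments   # last experiment: knockdown
      trt <- if (kd) "kd" else "treated"
      design <- experiment_design(
        conditions = c("control", trt),
        nc886_level = stats::setNames(c(if (kd) "high" else "low",
                                        if (kd) "low" else "high"),
                                      c("control", trt)),
        collection = mir,
        planted = stats::setNames(
          list(list(sets = planted_sets,
                    delta = if (kd) -cfg$planted_delta
                            else cfg$planted_delta)), trt),
        n_genes = cfg$n_genes, noise_sd = cfg$noise_sd,
        seed = cfg$seed + 200 + k)
      generate_experiment(design)
    })
    names(experiments) <- sprintf("exp%d", seq_len(cfg$n_experiments))
    list(mir = mir, tft = tft, experiments = experiments,
         planted_sets = planted_sets,
         orientations = c(rep(1, cfg$n_experiments - 1), -1))
  })
  logf("simulate: %d experiments of %d genes, %d planted MIR sets",
       cfg$n_experiments, cfg$n_genes, cfg$n_planted)

  ## stage: contrast -------------------------------------------------
  contrasts <- run_stage("contrast", {
    lapply(names(sim$experiments), function(nm) {
      x <- sim$experiments[[nm]]$matrix
      trt <- setdiff(unique(x$condition), "control")
      contrast(x, trt, "control")
    })
  })
  names(contrasts) <- names(sim$experiments)
  for (nm in names(contrasts)) {
    f <- file.path(outdir, sprintf("contrast_%s.csv", nm))
    write_contrast(contrasts[[nm]], f, cfg$p_cut, cfg$fc_cut)
    files[paste0("contrast_", nm)] <- f
    n_sel <- suppressMessages(
      length(select_significant(contrasts[[nm]], cfg$p_cut, cfg$fc_cut)))
    logf("contrast %s: %d genes in, %d selected (p < %g, |fc| >= %g)",
         nm, nrow(contrasts[[nm]]), n_sel, cfg$p_cut, cfg$fc_cut)
  }

  ## stage: gsa ------------------------------------------------------
  profiles <- run_stage("gsa", {
    lapply(contrasts, function(ct) list(
      mir = suppressMessages(profile_collection(ct, sim$mir,
                                                cfg$min_set_size)),
      tft = suppressMessages(profile_collection(ct, sim$tft,
                                                cfg$min_set_size))))
  })
  for (nm in names(profiles)) {
    for (coll in c("mir", "tft")) {
      f <- file.path(outdir, sprintf("zscores_%s_%s.csv", coll, nm))
      write_profile(profiles[[nm]][[coll]], f)
      files[paste0("zscores_", coll, "_", nm)] <- f
    }
    rd <- rank_distribution(profiles[[nm]]$mir)
    logf("gsa %s: MIR %d depleted / %d enriched, x-intercept rank %d",
         nm, rd$n_depleted, rd$n_enriched, rd$x_intercept_rank)
  }
  mir_rank <- run_stage("gsa", suppressMessages(
    rank_mirs(lapply(profiles, `[[`, "mir"), sim$orientations)))
  files["mir_ranking"] <- file.path(outdir, "mir_ranking.csv")
  utils::write.csv(mir_rank, files[["mir_ranking"]], row.names = FALSE,
                   quote = FALSE)

  ## stage: signature ------------------------------------------------
  sig <- run_stage("signature", suppressMessages(
    signature_genes(contrasts, sim$orientations,
                    fold_threshold = cfg$signature_fold,
                    min_experiments = cfg$min_experiments)))
  logf("signature: %d genes (fold %g in >= %d experiments)",
       nrow(sig), cfg$signature_fold, cfg$min_experiments)
  files["signature"] <- file.path(outdir, "signature_genes.csv")
  utils::write.csv(as.data.frame(sig), files[["signature"]],
                   row.names = FALSE, quote = FALSE)
  files["signature_gmt"] <- file.path(outdir, "signature.gmt")
  write_gmt(signature_to_collection(sig), files[["signature_gmt"]])

  ## stage: cohort ---------------------------------------------------
  # the synthetic cohort shares the derived signature's gene space, so
  # the trained classifier transfers by symbol as it would across real
  # platforms; a derived signature too small to classify with falls back
  # to the planted MIR member genes
  sig_genes <- if (nrow(sig) >= 5) sig$gene else
    unique(unlist(sim$mir$sets[sim$planted_sets], use.names = FALSE))
  sig_signs <- if (nrow(sig) >= 5) ifelse(sig$sign < 0, -1, 1) else
    rep(1, length(sig_genes))
  cohort <- run_stage("cohort", generate_cohort(cohort_design(
    n_patients = cfg$n_patients, prevalence = cfg$prevalence,
    signature_genes = sig_genes, signature_signs = sig_signs,
    delta_sig = cfg$delta_sig, noise_sd = cfg$noise_sd,
    baseline_hazard = cfg$baseline_hazard,
    hazard_ratio = cfg$hazard_ratio,
    censoring_rate = cfg$censoring_rate,
    p_resistant_high = cfg$p_resistant_high,
    p_resistant_low = cfg$p_resistant_low,
    seed = cfg$seed + 300)))
  logf("cohort: n = %d patients, %d signature genes shifted by %g",
       cfg$n_patients, length(sig_genes), cfg$delta_sig)
  files["truth"] <- file.path(outdir, "truth.json")
  write_truth(list(planted_sets = sim$planted_sets,
                   subtype = as.list(cohort$truth$subtype)),
              files[["truth"]])
  files["cohort_clinical"] <- file.path(outdir, "cohort_clinical.csv")
  write_clinical(cohort$clinical, files[["cohort_clinical"]])

  ## stage: train ----------------------------------------------------
  # training set: all experiment samples, labelled by the nc886 level
  # of their condition; values are taken relative to each experiment's
  # per-gene median so experiment-level baselines cancel before pooling
  train <- run_stage("train", {
    pooled <- do.call(cbind, lapply(sim$experiments, function(e) {
      v <- e$matrix$values
      v - apply(v, 1, stats::median)
    }))
    colnames(pooled) <- unlist(lapply(names(sim$experiments), function(nm)
      paste(nm, colnames(sim$experiments[[nm]]$matrix$values), sep = ".")))
    labels <- unlist(lapply(names(sim$experiments), function(nm) {
      e <- sim$experiments[[nm]]
      stats::setNames(
        unname(e$truth$nc886_level[e$matrix$condition]),
        paste(nm, colnames(e$matrix$values), sep = "."))
    }))
    xt <- expression_matrix(pooled, labels)  # condition = class label
    model <- suppressMessages(
      bccp_fit(xt, labels, sig_genes,
               cutoffs = c(low = cfg$low_cut, high = cfg$high_cut)))
    cv <- suppressMessages(bccp_loocv(xt, labels, sig_genes))
    list(model = model, cv = cv, xt = xt, labels = labels)
  })
  logf("train: %d genes, LOOCV misclassification rate %.3f",
       length(train$model$genes), train$cv$rate)
  files["model"] <- file.path(outdir, "bccp_model.json")
  bccp_to_json(train$model, files[["model"]])
  files["loocv"] <- file.path(outdir, "loocv.csv")
  utils::write.csv(train$cv$calls, files[["loocv"]], row.names = FALSE,
                   quote = FALSE)

  ## stage: classify -------------------------------------------------
  classified <- run_stage("classify",
                          bccp_classify(train$model, cohort$matrix))
  logf("classify: %d high / %d low / %d undetermined of %d patients",
       sum(classified$label == "high"), sum(classified$label == "low"),
       sum(classified$label == "undetermined"), nrow(classified))
  files["classification"] <- file.path(outdir, "classification.csv")
  utils::write.csv(as.data.frame(classified), files[["classification"]],
                   row.names = FALSE, quote = FALSE)

  ## stage: evaluate -------------------------------------------------
  report <- run_stage("evaluate", {
    clin <- cohort$clinical
    lab <- classified$label[match(clin$patient_id, classified$sample)]
    use <- lab != "undetermined"
    hi <- use & lab == "high"; lo <- use & lab == "low"
    lr <- logrank_test(clin$os_time[hi], clin$os_event[hi],
                       clin$os_time[lo], clin$os_event[lo])
    lr_rfs <- logrank_test(clin$rfs_time[hi], clin$rfs_event[hi],
                           clin$rfs_time[lo], clin$rfs_event[lo])
    km_high <- km_estimate(clin$os_time[hi], clin$os_event[hi])
    km_low <- km_estimate(clin$os_time[lo], clin$os_event[lo])
    known <- use & clin$chemo_response != "unknown"
    tab <- rbind(high = c(resistant = sum(known & lab == "high" &
                                            clin$chemo_response == "resistant"),
                          sensitive = sum(known & lab == "high" &
                                            clin$chemo_response == "sensitive")),
                 low = c(resistant = sum(known & lab == "low" &
                                           clin$chemo_response == "resistant"),
                         sensitive = sum(known & lab == "low" &
                                           clin$chemo_response == "sensitive")))
    chi <- contingency_test(tab)
    roc <- roc_auc(classified$p_high[match(clin$patient_id[known],
                                           classified$sample)],
                   clin$chemo_response[known] == "resistant",
                   seed = cfg$seed + 500)
    list(km_high = km_high, km_low = km_low,
         logrank_os = lr, logrank_rfs = lr_rfs,
         contingency = chi, roc = roc,
         n_analyzed = sum(use), n_undetermined = sum(!use))
  })
  logf("evaluate: OS log-rank chi2 %.3f p %.3g; chemo chi2 %.3f p %.3g; AUC %.3f",
       report$logrank_os$chi_square, report$logrank_os$p,
       report$contingency$chi_square, report$contingency$p,
       report$roc$auc)
  files["survival_curves"] <- file.path(outdir, "survival_curves.csv")
  km <- rbind(cbind(group = "high", as.data.frame(report$km_high)),
              cbind(group = "low", as.data.frame(report$km_low)))
  utils::write.csv(km, files[["survival_curves"]], row.names = FALSE,
                   quote = FALSE)
  files["report"] <- file.path(outdir, "report.json")
  jsonlite::write_json(
    list(n_analyzed = report$n_analyzed,
         n_undetermined = report$n_undetermined,
         logrank_os = report$logrank_os,
         logrank_rfs = report$logrank_rfs,
         chemo_table = report$contingency$counts,
         chemo_chi_square = report$contingency$chi_square,
         chemo_p = report$contingency$p,
         auc = report$roc$auc,
         auc_ci = c(report$roc$ci_lower, report$roc$ci_upper),
         loocv_rate = train$cv$rate),
    files[["report"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(files)
}
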