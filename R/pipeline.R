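## End-to-end experiment: cohort generation -> preprocessing -> training of
## all methods -> quantitative evaluation -> simulated-reader agreement.

#' Build an experiment configuration
#'
#' Two built-in profiles: `"paper"` mirrors the emulated protocol's scale
#' (207 cases split 120/37/50, 200 training epochs, all five U-Net depths);
#' `"fast"` is a scaled-down profile (35 cases, 30 epochs, U-Net L4 only)
#' for desk-scale runs.
#'
#' @param profile `"fast"` or `"paper"`.
#' @param seed master seed; every downstream stage derives its own seed from
#'   it.
#' @param output_dir optional directory for report files (created on run).
#' @param overrides named list merged over the profile defaults (e.g.
#'   `list(n_cases = 10, epochs = 2, methods = c("short", "unet_l1"))`).
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(profile = c("fast", "paper"), seed = 1L,
                              output_dir = NULL, overrides = NULL) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    n_cases = if (profile == "paper") 207L else 35L,
    pattern_prevalence = c(0.17, 0.29, 0.28, 0.26),
    spec = phantom_spec(),
    fractions = c(120, 37, 50) / 207,
    methods = if (profile == "paper")
      c("short", "gaussian", "bilateral", paste0("unet_l", 1:5))
    else c("short", "gaussian", "bilateral", "unet_l4"),
    reference_method = "unet_l4",
    epochs = if (profile == "paper") 200L else 30L,
    batch_size = 8L,
    lr_initial = 1e-3, lr_late = 1e-5, lr_switch_epoch = 150L,
    n_readers = 3L,
    # simulated-reader confusion: sharper on enhanced images than on the raw
    # short images, mirroring the direction of the emulated reader study
    reader_accuracy = c(short = 0.55, gaussian = 0.65, bilateral = 0.65,
                        unet = 0.85, truth = 1.0),
    output_dir = output_dir,
    master_seed = as.integer(seed))
  for (nm in names(overrides %||% list())) cfg[[nm]] <- overrides[[nm]]
  bad <- setdiff(cfg$methods, names(model_registry()))
  if (length(bad)) stop("unknown method id(s): ", paste(bad, collapse = ", "))
  if (abs(sum(cfg$fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' The file may set any [experiment_config()] field; `phantom:` entries are
#' applied to the phantom spec.
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- y$profile %||% "fast"
  seed <- y$master_seed %||% 1L
  phantom_over <- y$phantom %||% list()
  y$profile <- NULL; y$master_seed <- NULL; y$phantom <- NULL
  cfg <- experiment_config(profile, seed = seed, overrides = y)
  if (length(phantom_over))
    cfg$spec <- do.call(phantom_spec, utils::modifyList(
      unclass(cfg$spec)[names(formals(phantom_spec))], phantom_over))
  cfg
}

.reader_accuracy_for <- function(cfg, method_id) {
  acc <- cfg$reader_accuracy
  if (method_id %in% names(acc)) return(acc[[method_id]])
  if (grepl("^unet", method_id)) return(acc[["unet"]])
  stop("no reader accuracy configured for method ", method_id)
}

#' Run the full experiment
#'
#' Stages: phantom cohort generation; preprocessing and case-level split;
#' training of every U-Net method and application of the filter baselines;
#' per-slice PSNR/SSIM with Friedman and Dunn-Holm statistics; simulated
#' readers scored against the phantom ground truth (weighted kappa,
#' intra-/inter-rater ICC). Fully deterministic given the config and master
#' seed. If `config$output_dir` is set, CSV reports, text tables, model
#' checkpoints and a run log are written there.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return a result bundle (invisible list): `metric_table`, `summary`,
#'   `friedman`, `dunn`, `kappa`, `icc_intra`, `icc_inter`, `scores`,
#'   `partition`, `models`, `config`.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$master_seed
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("[%s] done in %.1fs", name,
        as.numeric(Sys.time() - t0, units = "secs"))
    r
  }

  cohort <- stage("generate", generate_cohort(
    config$n_cases, config$pattern_prevalence, config$spec,
    seed = derive_seed(seed, 1L)))
  prep <- stage("preprocess", preprocess_cohort(
    cohort, config$fractions, seed = derive_seed(seed, 2L)))
  part_of <- function(p) Filter(function(s) s$partition == p, prep$samples)
  train_s <- part_of("train"); val_s <- part_of("validation")
  test_s <- part_of("test")
  say("samples: %d train / %d validation / %d test",
      length(train_s), length(val_s), length(test_s))

  registry <- model_registry()
  models <- list()
  outputs <- list()
  for (m in config$methods) {
    def <- registry[[m]]
    if (def$kind == "unet") {
      tc <- train_config(epochs = config$epochs,
                         batch_size = config$batch_size,
                         lr_initial = config$lr_initial,
                         lr_late = config$lr_late,
                         lr_switch_epoch = config$lr_switch_epoch,
                         seed = derive_seed(seed, 4L, def$depth))
      net <- build_unet(def$depth, seed = derive_seed(seed, 3L, def$depth))
      models[[m]] <- stage(paste0("train:", m),
                           train_unet(net, train_s, val_s, tc))
      outputs[[m]] <- apply_method(m, test_s, model = models[[m]],
                                   registry = registry)
    } else {
      outputs[[m]] <- stage(paste0("apply:", m),
                            apply_method(m, test_s, registry = registry))
    }
  }

  mt <- stage("evaluate", evaluate_methods(
    outputs, test_s, reference_method = config$reference_method))
  summary_df <- summarize_metrics(mt)
  fried <- lapply(c(psnr = "psnr", ssim = "ssim"),
                  function(me) friedman_test(mt, me))
  dunn <- if (config$reference_method %in% config$methods)
    lapply(c(psnr = "psnr", ssim = "ssim"),
           function(me) dunn_holm(mt, me, config$reference_method))
  else NULL

  # --- simulated reader study on the test cases -----------------------------
  test_ids <- names(prep$partition)[prep$partition == "test"]
  truth_test <- cohort$truth[cohort$truth$case_id %in% test_ids, ]
  gold <- score_table("gold", truth_test$case_id, truth_test$hemisphere,
                      "truth", 1L, truth_test$score)
  scores <- stage("agree", {
    acc_tabs <- list()
    for (m in config$methods) {
      conf <- adjacent_confusion(.reader_accuracy_for(config, m))
      for (r in seq_len(config$n_readers)) {
        rid <- paste0("reader_", LETTERS[r])
        acc_tabs[[length(acc_tabs) + 1L]] <- simulate_reader(
          gold, conf, seed = derive_seed(seed, 5L, match(m, config$methods), r),
          reader_id = rid, method_id = m, session = 1L)
        if (m == config$reference_method) {
          acc_tabs[[length(acc_tabs) + 1L]] <- simulate_reader(
            gold, conf,
            seed = derive_seed(seed, 6L, match(m, config$methods), r),
            reader_id = rid, method_id = m, session = 2L)
        }
      }
    }
    validate_score_table(do.call(rbind, acc_tabs))
  })
  kap <- kappa_report(scores, gold)
  icc_intra <- if (config$reference_method %in% config$methods)
    intra_rater_report(scores, config$reference_method) else NULL
  icc_inter <- inter_rater_report(scores)

  bundle <- list(metric_table = mt, summary = summary_df, friedman = fried,
                 dunn = dunn, kappa = kap, icc_intra = icc_intra,
                 icc_inter = icc_inter, scores = scores,
                 partition = prep$partition, models = models,
                 truth = cohort$truth, config = config)
  if (!is.null(config$output_dir))
    write_experiment_reports(bundle, config$output_dir)
  invisible(bundle)
}

#' Write the report files of a finished experiment
#'
#' @param bundle a [run_experiment()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment_reports <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE)
  w(data.frame(case_id = names(bundle$partition),
               partition = unname(bundle$partition)), "partition.csv")
  w(bundle$truth, "truth.csv")
  w(as.data.frame(bundle$metric_table), "metrics.csv")
  w(bundle$summary, "metric_summary.csv")
  w(bundle$kappa$per_reader, "kappa.csv")
  if (!is.null(bundle$icc_intra)) w(bundle$icc_intra, "icc_intra.csv")
  w(bundle$icc_inter$pairs, "icc_inter.csv")
  w(as.data.frame(bundle$scores), "scores.csv")
  dir.create(file.path(dir, "models"), showWarnings = FALSE)
  for (m in names(bundle$models)) {
    saveRDS(bundle$models[[m]],
            file.path(dir, "models", paste0(m, ".rds")))
    utils::write.csv(bundle$models[[m]]$history,
                     file.path(dir, "models", paste0(m, "_history.csv")),
                     row.names = FALSE)
  }
  writeLines(report_tables(bundle), file.path(dir, "report.txt"))
  cfg <- bundle$config
  cfg$spec <- unclass(cfg$spec)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  log <- c(sprintf("master_seed: %d", bundle$config$master_seed),
           sprintf("finished: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

.fmt_mean_sd <- function(mean, sd, digits = 3) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), mean, sd)
}

.fmt_p <- function(p) {
  ifelse(p >= 0.9995, "1.0",
         ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p)))
}

#' Format the result bundle as human-readable tables
#'
#' Mean +/- SD to 3 decimals for PSNR and SSIM, kappa to 3 decimals, Holm
#' p-values against the reference method; p at or above 0.9995 prints as
#' "1.0".
#'
#' @param bundle a [run_experiment()] result.
#' @return character vector of report lines.
#' @export
report_tables <- function(bundle) {
  ref <- bundle$config$reference_method
  lines <- character(0)
  for (metric in c("psnr", "ssim")) {
    s <- bundle$summary[bundle$summary$metric == metric, ]
    lines <- c(lines, toupper(metric), paste(rep("-", 48), collapse = ""))
    for (i in seq_len(nrow(s))) {
      m <- s$method_id[i]
      pcol <- if (!is.null(bundle$dunn) && m != ref) {
        d <- bundle$dunn[[metric]]
        .fmt_p(d$holm_p[d$method_id == m])
      } else ""
      lines <- c(lines, sprintf("%-12s %18s  %s", m,
                                .fmt_mean_sd(s$mean[i], s$sd[i]), pcol))
    }
    if (!is.null(bundle$friedman[[metric]]))
      lines <- c(lines, sprintf("Friedman chi-sq = %.3f, p = %s",
                                bundle$friedman[[metric]]$statistic,
                                .fmt_p(bundle$friedman[[metric]]$p_value)),
                 "")
  }
  if (!is.null(bundle$kappa)) {
    lines <- c(lines, "Weighted kappa vs gold standard",
               paste(rep("-", 48), collapse = ""))
    km <- bundle$kappa$per_reader
    readers <- sort(unique(km$reader_id))
    hdr <- sprintf("%-12s %s  average", "method",
                   paste(sprintf("%8s", readers), collapse = " "))
    lines <- c(lines, hdr)
    for (m in unique(km$method_id)) {
      vals <- vapply(readers, function(r)
        km$kappa[km$reader_id == r & km$method_id == m][1], numeric(1))
      lines <- c(lines, sprintf("%-12s %s  %7.3f", m,
                                paste(sprintf("%8.3f", vals), collapse = " "),
                                mean(vals)))
    }
    lines <- c(lines, "")
  }
  if (!is.null(bundle$icc_intra)) {
    lines <- c(lines, "Intra-rater ICC(2,1)",
               paste(rep("-", 48), collapse = ""),
               sprintf("%-12s %7.3f", bundle$icc_intra$reader_id,
                       bundle$icc_intra$icc),
               sprintf("%-12s %7.3f", "average", mean(bundle$icc_intra$icc)),
               "")
  }
  if (!is.null(bundle$icc_inter)) {
    p <- bundle$icc_inter$pairs
    lines <- c(lines, "Inter-rater ICC(2,1)",
               paste(rep("-", 48), collapse = ""),
               sprintf("%s-%s %7.3f", p$reader_a, p$reader_b, p$icc),
               sprintf("%-12s %7.3f", "average", bundle$icc_inter$average))
  }
  lines
}
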