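RUN_CONFIG_KEYS <- c("network", "n_per_group", "alphas", "avt_method",
                     "signed_weights", "out_dir", "master_seed",
                     "ar1_coefficient", "noise_sd", "task_amplitude",
                     "input_dir", "log_level")

#' Validate a pipeline run configuration
#'
#' Reads a YAML configuration file (or takes a list) and returns a fully
#' typed, range-checked `run_config`. Unknown keys are rejected by name;
#' out-of-order alpha lists are sorted with a warning; omitted fields take
#' the documented defaults.
#'
#' Recognized keys: `network` ("N1"/"N2" or a node-table TSV path),
#' `n_per_group`, `alphas`, `avt_method` ("mean"/"eigenvariate"),
#' `signed_weights`, `out_dir`, `master_seed`, `ar1_coefficient`,
#' `noise_sd`, `task_amplitude`, `input_dir` (pre-simulated cohort instead
#' of fresh simulation), `log_level` ("quiet"/"info").
#'
#' @param config Path to a YAML file, or a named list.
#' @return A `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(names(config)) ||
      !length(config)) {
    stop("config error: missing required fields (empty or non-mapping ",
         "configuration)", call. = FALSE)
  }
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  errors <- character(0)
  cfg <- list(
    network = config$network %||% "N1",
    n_per_group = config$n_per_group %||% 16,
    alphas = as.numeric(config$alphas %||% GTNA_ALPHAS),
    avt_method = config$avt_method %||% "mean",
    signed_weights = config$signed_weights %||% TRUE,
    out_dir = config$out_dir %||% "bimanet-run",
    master_seed = config$master_seed %||% 1L,
    ar1_coefficient = config$ar1_coefficient %||% 0.3,
    noise_sd = config$noise_sd %||% 1,
    task_amplitude = config$task_amplitude %||% 0.5,
    input_dir = config$input_dir,
    log_level = config$log_level %||% "info")
  if (!cfg$network %in% c("N1", "N2") && !file.exists(cfg$network)) {
    errors <- c(errors, sprintf(
      "network must be 'N1', 'N2' or an existing node-table path, got '%s'",
      cfg$network))
  }
  if (!is.numeric(cfg$n_per_group) || cfg$n_per_group < 2 ||
      cfg$n_per_group != round(cfg$n_per_group)) {
    errors <- c(errors, "n_per_group must be an integer >= 2")
  }
  if (!length(cfg$alphas) || anyNA(cfg$alphas) ||
      any(cfg$alphas <= 0 | cfg$alphas >= 1)) {
    errors <- c(errors, "alphas must all lie in (0, 1)")
  } else if (is.unsorted(cfg$alphas)) {
    warning("alphas were not sorted ascending; normalizing", call. = FALSE)
    cfg$alphas <- sort(cfg$alphas)
  }
  if (!cfg$avt_method %in% c("mean", "eigenvariate")) {
    errors <- c(errors, "avt_method must be 'mean' or 'eigenvariate'")
  }
  if (!is.logical(cfg$signed_weights)) {
    errors <- c(errors, "signed_weights must be true/false")
  }
  if (!is.numeric(cfg$ar1_coefficient) || cfg$ar1_coefficient < 0 ||
      cfg$ar1_coefficient >= 1) {
    errors <- c(errors, "ar1_coefficient must lie in [0, 1)")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    errors <- c(errors, "noise_sd must be positive")
  }
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir)) {
    errors <- c(errors, sprintf("input_dir does not exist: '%s'",
                                cfg$input_dir))
  }
  if (!cfg$log_level %in% c("quiet", "info")) {
    errors <- c(errors, "log_level must be 'quiet' or 'info'")
  }
  if (length(errors)) {
    stop("config error(s):\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$n_per_group <- as.integer(cfg$n_per_group)
  cfg$master_seed <- as.integer(cfg$master_seed)
  structure(cfg, class = "run_config")
}

pipeline_log <- function(cfg, stage, ...) {
  if (identical(cfg$log_level, "info")) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output table, skipping the config-hash stamp
#'
#' @param path Path to a CSV written by [run_pipeline()].
#' @return Data frame.
#' @export
read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# load a cohort previously written by write_cohort()
read_cohort_series <- function(dir, n_per_group) {
  series <- list()
  for (group in c("old", "young")) {
    series[[group]] <- vector("list", n_per_group)
    for (s in seq_len(n_per_group)) {
      series[[group]][[s]] <- list()
      for (cond in c("AP", "IP")) {
        fn <- file.path(dir, sprintf("%s%02d_%s.tsv", group, s, cond))
        if (!file.exists(fn)) {
          stop(sprintf("stage load: missing series file for %s subject %d ",
                       group, s), fn, call. = FALSE)
        }
        mat <- t(as.matrix(utils::read.delim(fn, check.names = FALSE)))
        series[[group]][[s]][[cond]] <- mat
      }
    }
  }
  kin_path <- file.path(dir, "kinematics.tsv")
  kinematics <- if (file.exists(kin_path)) {
    utils::read.delim(kin_path, stringsAsFactors = FALSE)
  }
  list(series = series, kinematics = kinematics)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> partial correlations -> multi-alpha
#' thresholding -> graph metrics -> group statistics from a single
#' configuration, writing all result tables and a manifest into
#' `out_dir`. Outputs per alpha: subject-level edge counts, nodal and
#' network metric tables, AGE x PHASE ANOVA tables, interhemispheric
#' strength analysis (ANOVA + Tukey post hoc), and kinematics correlation
#' tables. Every table carries the configuration hash in a leading comment
#' line; re-running with the same config and seed reproduces all outputs
#' byte-identically.
#'
#' @param config A `run_config`, a list, or a YAML path (passed through
#'   [validate_config()]).
#' @return Invisibly, a list with the in-memory tables (`edge_counts`,
#'   `network_metrics`, `nodal_metrics`, `anova`, `interhemispheric`,
#'   `interhemispheric_anova`, `tukey`, `correlations`, `manifest`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(if (inherits(config, "run_config")) {
    unclass(config)
  } else config)
  # hash the scientific configuration only: where results are written (or
  # how chattily) must not change what they are
  hash_keys <- setdiff(RUN_CONFIG_KEYS, c("out_dir", "log_level"))
  hash <- config_hash(unclass(cfg)[hash_keys[hash_keys %in% names(cfg)]])
  node_table <- if (cfg$network %in% c("N1", "N2")) {
    load_node_table(node_table_path(cfg$network), cfg$network)
  } else {
    load_node_table(cfg$network)
  }
  n_nodes <- nrow(node_table)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- cohort_spec(
    n_per_group = cfg$n_per_group,
    group_models = default_group_models(
      n_nodes = n_nodes, seed = derive_seed(cfg$master_seed, "models")),
    noise_sd = cfg$noise_sd, ar1_coefficient = cfg$ar1_coefficient,
    task_amplitude = cfg$task_amplitude, master_seed = cfg$master_seed)

  if (is.null(cfg$input_dir)) {
    pipeline_log(cfg, "simulate", "cohort of 2 x %d subjects, %d nodes",
                 cfg$n_per_group, n_nodes)
    sim <- simulate_cohort(cohort)
  } else {
    pipeline_log(cfg, "load", "cohort from %s", cfg$input_dir)
    sim <- read_cohort_series(cfg$input_dir, cfg$n_per_group)
  }

  edge_rows <- list(); net_rows <- list(); nodal_rows <- list()
  inter_rows <- list()
  for (group in c("old", "young")) {
    for (s in seq_len(cfg$n_per_group)) {
      sid <- sprintf("%s%02d", group, s)
      for (cond in c("AP", "IP")) {
        mat <- sim$series[[group]][[s]][[cond]]
        if (is.null(mat)) {
          stop(sprintf("stage connectivity: missing series for %s/%s",
                       sid, cond), call. = FALSE)
        }
        pcm <- tryCatch(partial_correlation(mat), error = function(e) {
          stop(sprintf("stage connectivity failed for %s/%s: %s", sid, cond,
                       conditionMessage(e)), call. = FALSE)
        })
        for (alpha in cfg$alphas) {
          g <- suppressMessages(
            threshold_network(pcm, alpha, signed = cfg$signed_weights))
          m <- graph_metrics(g)
          edge_rows[[length(edge_rows) + 1]] <- data.frame(
            subject_id = sid, group = group, condition = cond,
            alpha = alpha, n_edges = m$network$n_edges)
          net_rows[[length(net_rows) + 1]] <- cbind(
            data.frame(subject_id = sid, group = group, condition = cond,
                       alpha = alpha), m$network)
          nodal_rows[[length(nodal_rows) + 1]] <- cbind(
            data.frame(subject_id = sid, group = group, condition = cond,
                       alpha = alpha), m$nodal)
          inter_rows[[length(inter_rows) + 1]] <- data.frame(
            subject_id = sid, group = group, condition = cond,
            alpha = alpha,
            strength = interhemispheric_strength(g, node_table))
        }
        pipeline_log(cfg, "analyze", "%s %s done (%d alphas)", sid, cond,
                     length(cfg$alphas))
      }
    }
  }
  edge_counts <- do.call(rbind, edge_rows)
  network_metrics <- do.call(rbind, net_rows)
  nodal_metrics <- do.call(rbind, nodal_rows)
  interhemispheric <- do.call(rbind, inter_rows)

  measures <- c("degree", "density", "strength", "cluster_coef",
                "local_efficiency", "global_efficiency", "path_length",
                "betweenness", "swn_cluster_coef", "swn_path_length")
  anova_rows <- list()
  for (alpha in cfg$alphas) {
    sub <- network_metrics[network_metrics$alpha == alpha, ]
    for (meas in measures) {
      rec <- data.frame(subject_id = sub$subject_id, group = sub$group,
                        condition = sub$condition, value = sub[[meas]],
                        stringsAsFactors = FALSE)
      if (anyNA(rec$value)) next # e.g. SWN undefined at sparse alphas
      fit <- mixed_anova(rec)
      fit$measure <- meas
      fit$alpha <- alpha
      anova_rows[[length(anova_rows) + 1]] <- fit
    }
  }
  anova_table <- do.call(rbind, anova_rows)
  anova_table$sig_05 <- anova_table$p < 0.05
  anova_table$sig_001 <- anova_table$p < 0.001

  # interhemispheric sub-analysis at the primary alpha (0.001 if present)
  primary_alpha <- if (any(abs(cfg$alphas - 0.001) < 1e-12)) {
    0.001
  } else cfg$alphas[ceiling(length(cfg$alphas) / 2)]
  inter_sub <- interhemispheric[
    abs(interhemispheric$alpha - primary_alpha) < 1e-12, ]
  inter_rec <- data.frame(subject_id = inter_sub$subject_id,
                          group = inter_sub$group,
                          condition = inter_sub$condition,
                          value = inter_sub$strength,
                          stringsAsFactors = FALSE)
  inter_anova <- NULL; tukey <- NULL
  if (!anyNA(inter_rec$value)) {
    inter_anova <- mixed_anova(inter_rec)
    tukey <- tukey_posthoc(inter_rec)
  } else {
    pipeline_log(cfg, "stats",
                 "interhemispheric ANOVA skipped: subjects without %s",
                 "crossing edges at the primary alpha")
  }

  correlations <- NULL
  if (!is.null(sim$kinematics)) {
    prim <- network_metrics[
      abs(network_metrics$alpha - primary_alpha) < 1e-12, ]
    metric_long <- do.call(rbind, lapply(measures, function(meas) {
      data.frame(subject_id = prim$subject_id, group = prim$group,
                 condition = prim$condition, measure = meas,
                 value = prim[[meas]], stringsAsFactors = FALSE)
    }))
    correlations <- kinematics_correlations(metric_long, sim$kinematics)
  }

  write_stamped_csv(edge_counts, file.path(cfg$out_dir, "edge_counts.csv"),
                    hash)
  write_stamped_csv(network_metrics,
                    file.path(cfg$out_dir, "network_metrics.csv"), hash)
  write_stamped_csv(nodal_metrics,
                    file.path(cfg$out_dir, "nodal_metrics.csv"), hash)
  write_stamped_csv(anova_table, file.path(cfg$out_dir, "anova.csv"), hash)
  write_stamped_csv(interhemispheric,
                    file.path(cfg$out_dir, "interhemispheric.csv"), hash)
  if (!is.null(inter_anova)) {
    write_stamped_csv(inter_anova,
                      file.path(cfg$out_dir, "interhemispheric_anova.csv"),
                      hash)
    write_stamped_csv(tukey,
                      file.path(cfg$out_dir, "interhemispheric_tukey.csv"),
                      hash)
  }
  if (!is.null(correlations)) {
    write_stamped_csv(correlations,
                      file.path(cfg$out_dir, "kinematics_correlations.csv"),
                      hash)
  }
  manifest <- list(
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
    config_hash = hash,
    package_version = as.character(utils::packageVersion("bimanet")),
    n_nodes = n_nodes,
    network_id = attr(node_table, "network_id"),
    primary_alpha = primary_alpha,
    conventions = list(
      weights = if (cfg$signed_weights) "signed" else "absolute",
      significance_df = "n_samples - N",
      betweenness = "unordered pairs, unnormalized",
      unreachable_pairs = "excluded from L_i",
      avt_method = cfg$avt_method))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(cfg, "report", "wrote tables to %s", cfg$out_dir)
  invisible(list(edge_counts = edge_counts,
                 network_metrics = network_metrics,
                 nodal_metrics = nodal_metrics, anova = anova_table,
                 interhemispheric = interhemispheric,
                 interhemispheric_anova = inter_anova, tukey = tukey,
                 correlations = correlations, manifest = manifest))
}
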