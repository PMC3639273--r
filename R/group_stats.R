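check_records <- function(records) {
  needed <- c("subject_id", "group", "condition", "value")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  groups <- sort(unique(records$group))
  conds <- sort(unique(records$condition))
  if (length(groups) != 2 || length(conds) != 2) {
    stop("records must contain exactly two groups and two conditions",
         call. = FALSE)
  }
  tab <- table(records$subject_id, records$condition)
  incomplete <- rownames(tab)[rowSums(tab == 1) != 2 | rowSums(tab) != 2]
  if (length(incomplete)) {
    stop("subjects without exactly one value per condition: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  grp_of <- tapply(records$group, records$subject_id,
                   function(g) unique(g))
  if (any(lengths(grp_of) != 1)) {
    stop("subjects assigned to more than one group", call. = FALSE)
  }
  n_per_group <- table(unlist(grp_of))
  if (length(unique(n_per_group)) != 1) {
    stop("groups are unbalanced: ",
         paste(sprintf("%s=%d", names(n_per_group), n_per_group),
               collapse = ", "), call. = FALSE)
  }
  list(groups = groups, conds = conds, n = unname(n_per_group[1]))
}

#' Split-plot AGE x PHASE mixed ANOVA
#'
#' Two-by-two mixed ANOVA with a between-subjects factor (`group`, e.g.
#' AGE old/young) and a within-subjects factor (`condition`, e.g. PHASE
#' AP/IP). The between effect is tested against the subjects-within-groups
#' error stratum; the within effect and the interaction are tested against
#' the subject-by-condition stratum, as the split-plot design requires.
#' The input must be balanced and complete (every subject measured in both
#' conditions).
#'
#' Degenerate inputs are flagged rather than hidden: a zero effect sum of
#' squares gives `F = 0, p = 1`; a nonzero effect over a zero error mean
#' square gives `F = Inf, p = 0`.
#'
#' @param records Data frame with columns `subject_id`, `group`,
#'   `condition`, `value` (one row per subject-condition).
#' @return Data frame with rows for the between effect (`AGE`), within
#'   effect (`PHASE`) and interaction (`AGE:PHASE`): columns `effect`, `F`,
#'   `df_num`, `df_den`, `p`.
#' @examples
#' rec <- expand.grid(subject_id = sprintf("s%d", 1:8),
#'                    condition = c("AP", "IP"))
#' rec$group <- rep(rep(c("old", "young"), each = 4), 2)
#' set.seed(1); rec$value <- rnorm(nrow(rec))
#' mixed_anova(rec)
#' @export
mixed_anova <- function(records) {
  info <- check_records(records)
  groups <- info$groups
  conds <- info$conds
  n <- info$n # subjects per group
  a <- 2; b <- 2
  N_s <- a * n
  y <- records$value
  if (anyNA(y)) stop("records contain missing values", call. = FALSE)
  grand <- mean(y)
  subj_mean <- tapply(y, records$subject_id, mean)
  grp_mean <- tapply(y, records$group, mean)
  cond_mean <- tapply(y, records$condition, mean)
  cell_mean <- tapply(y, list(records$group, records$condition), mean)

  ss_between_subjects <- b * sum((subj_mean - grand)^2)
  ss_age <- n * b * sum((grp_mean - grand)^2)
  ss_subj_within <- ss_between_subjects - ss_age

  ss_total <- sum((y - grand)^2)
  ss_within <- ss_total - ss_between_subjects
  ss_phase <- N_s * sum((cond_mean - grand)^2)
  interaction_dev <- sweep(sweep(cell_mean, 1, grp_mean[rownames(cell_mean)]),
                           2, cond_mean[colnames(cell_mean)]) + grand
  ss_interaction <- n * sum(interaction_dev^2)
  ss_err_within <- ss_within - ss_phase - ss_interaction

  df_subj <- a * (n - 1)
  df_err_within <- (b - 1) * a * (n - 1)

  f_and_p <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_eff <= 1e-300) return(c(F = 0, p = 1))
    ms_eff <- ss_eff / df_eff
    ms_err <- ss_err / df_err
    if (ms_err <= 1e-300) return(c(F = Inf, p = 0))
    Fv <- ms_eff / ms_err
    c(F = Fv, p = stats::pf(Fv, df_eff, df_err, lower.tail = FALSE))
  }
  age <- f_and_p(ss_age, 1, ss_subj_within, df_subj)
  phase <- f_and_p(ss_phase, 1, ss_err_within, df_err_within)
  inter <- f_and_p(ss_interaction, 1, ss_err_within, df_err_within)

  out <- data.frame(
    effect = c("AGE", "PHASE", "AGE:PHASE"),
    F = c(age["F"], phase["F"], inter["F"]),
    df_num = 1L,
    df_den = c(df_subj, df_err_within, df_err_within),
    p = c(age["p"], phase["p"], inter["p"]),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "ss") <- c(total = ss_total, age = ss_age,
                       subjects_within_groups = ss_subj_within,
                       phase = ss_phase, interaction = ss_interaction,
                       error_within = ss_err_within)
  attr(out, "cell_means") <- cell_mean
  attr(out, "n_per_group") <- n
  out
}

#' Mean interhemispheric connection strength of a graph
#'
#' Average weight over the valid edges whose endpoints lie in different
#' hemispheres (the connections that "travel" between hemispheres). A graph
#' without any crossing edge yields `NA` — an absent observation, never an
#' implicit 0.
#'
#' @param graph A `network_graph` built on the node order of `node_table`.
#' @param node_table The `node_table` supplying hemisphere labels.
#' @return Single numeric mean strength, or `NA_real_`.
#' @export
interhemispheric_strength <- function(graph, node_table) {
  stopifnot(inherits(graph, "network_graph"),
            inherits(node_table, "node_table"))
  if (nrow(node_table) != nrow(graph$binary)) {
    stop("node table and graph disagree on node count", call. = FALSE)
  }
  pairs <- interhemispheric_pairs(node_table)
  if (!nrow(pairs)) return(NA_real_)
  on_edge <- graph$binary[pairs] == 1
  if (!any(on_edge)) return(NA_real_)
  mean(graph$weights[pairs][on_edge])
}

#' Tukey HSD post hoc comparisons of the four AGE x PHASE cells
#'
#' Studentized-range-adjusted pairwise comparisons of the four cell means of
#' the split-plot design. Comparisons within a group (AP vs. IP for the same
#' subjects) use the within-subject error stratum; comparisons across groups
#' involve the subject variance as well and use the composite error
#' `(MS_subjects + MS_within) / 2` with Satterthwaite degrees of freedom.
#' The adjusted p-value is `ptukey(q, nmeans = 4, df)`.
#'
#' @param records Data frame as for [mixed_anova()].
#' @param comparisons Optional character matrix / data frame with two
#'   columns of cell labels (`"group.condition"`); default all six pairs.
#' @return Data frame: `cell_a`, `cell_b`, `diff`, `se`, `q`, `df`,
#'   `p_adj`, `stratum`.
#' @export
tukey_posthoc <- function(records, comparisons = NULL) {
  fit <- mixed_anova(records)
  ss <- attr(fit, "ss")
  cells <- attr(fit, "cell_means")
  n <- attr(fit, "n_per_group")
  a <- 2; b <- 2
  ms_subj <- ss[["subjects_within_groups"]] / (a * (n - 1))
  ms_within <- ss[["error_within"]] / ((b - 1) * a * (n - 1))
  df_within <- (b - 1) * a * (n - 1)
  df_subj <- a * (n - 1)

  labels <- as.vector(outer(rownames(cells), colnames(cells), paste,
                            sep = "."))
  means <- as.vector(cells)
  names(means) <- labels
  if (is.null(comparisons)) {
    idx <- utils::combn(labels, 2)
    comparisons <- t(idx)
  }
  comparisons <- as.matrix(comparisons)
  res <- apply(comparisons, 1, function(cmp) {
    ga <- sub("\\..*$", "", cmp[1]); gb <- sub("\\..*$", "", cmp[2])
    within_group <- identical(ga, gb)
    if (within_group) {
      var_mean <- ms_within / n
      df <- df_within
      stratum <- "within"
    } else {
      var_mean <- (ms_subj + ms_within) / (2 * n)
      # Satterthwaite for the (MS_subj + MS_within)/2 composite
      num <- (ms_subj + ms_within)^2
      den <- ms_subj^2 / df_subj + ms_within^2 / df_within
      df <- if (den > 0) num / den else df_subj
      stratum <- "between"
    }
    d <- means[cmp[1]] - means[cmp[2]]
    se <- sqrt(var_mean)
    if (se <= 1e-300) {
      q <- if (abs(d) <= 1e-300) 0 else Inf
    } else {
      q <- abs(d) / se
    }
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = length(labels), df = df,
                    lower.tail = FALSE)
    c(diff = unname(d), se = se, q = unname(q), df = df, p_adj = unname(p),
      stratum = stratum)
  })
  out <- data.frame(
    cell_a = comparisons[, 1], cell_b = comparisons[, 2],
    diff = as.numeric(res["diff", ]), se = as.numeric(res["se", ]),
    q = as.numeric(res["q", ]), df = as.numeric(res["df", ]),
    p_adj = as.numeric(res["p_adj", ]), stratum = res["stratum", ],
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Correlations between connectivity metrics and kinematics
#'
#' Pearson correlations between subject-level network metrics and the two
#' kinematic outcomes (phase error, SD of relative phase), evaluated per
#' group and condition. A correlation is flagged significant when its
#' two-sided p-value falls below `alpha_sig` (default 0.01). Zero-variance
#' inputs yield a missing R with the reason recorded. The number of
#' evaluated correlations is attached so readers can apply a
#' multiple-testing correction of their choice.
#'
#' @param metrics Data frame with columns `subject_id`, `group`,
#'   `condition`, `measure`, `value`.
#' @param kinematics Data frame with columns `subject_id`, `group`,
#'   `condition`, and one column per kinematic outcome (e.g. `phase_error`,
#'   `phase_sd`).
#' @param alpha_sig Significance level for the flag (default 0.01).
#' @return Data frame: `measure`, `kinematic`, `group`, `condition`, `n`,
#'   `R`, `p`, `significant`, `note`; attribute `n_correlations`.
#' @export
kinematics_correlations <- function(metrics, kinematics,
                                    alpha_sig = 0.01) {
  kin_cols <- setdiff(names(kinematics),
                      c("subject_id", "group", "condition"))
  out <- list()
  for (meas in unique(metrics$measure)) {
    for (kc in kin_cols) {
      for (grp in unique(metrics$group)) {
        for (cond in unique(metrics$condition)) {
          m <- metrics[metrics$measure == meas & metrics$group == grp &
                         metrics$condition == cond, ]
          k <- kinematics[kinematics$group == grp &
                            kinematics$condition == cond,
                          c("subject_id", kc)]
          merged <- merge(m[, c("subject_id", "value")], k,
                          by = "subject_id")
          merged <- merged[stats::complete.cases(merged), ]
          n_pair <- nrow(merged)
          row <- data.frame(measure = meas, kinematic = kc, group = grp,
                            condition = cond, n = n_pair, R = NA_real_,
                            p = NA_real_, significant = FALSE, note = "",
                            stringsAsFactors = FALSE)
          if (n_pair >= 3) {
            if (stats::sd(merged$value) == 0 ||
                stats::sd(merged[[kc]]) == 0) {
              row$note <- "zero variance"
            } else {
              ct <- stats::cor.test(merged$value, merged[[kc]],
                                    method = "pearson")
              row$R <- unname(ct$estimate)
              row$p <- ct$p.value
              row$significant <- ct$p.value < alpha_sig
            }
          } else {
            row$note <- "fewer than 3 complete pairs"
          }
          out[[length(out) + 1]] <- row
        }
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "n_correlations") <- nrow(res)
  attr(res, "alpha_sig") <- alpha_sig
  res
}
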