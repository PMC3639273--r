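#' Block-design specification
#'
#' Describes the scanning design of a block-design bimanual coordination
#' session: alternating blocks of anti-phase (AP), in-phase (IP) and rest
#' conditions. At the defaults — 4 runs of 6 blocks per condition, 7 scans
#' per 21-s block at TR = 3 s — each run lasts 126 scans = 378 s, and each
#' condition contributes 42 scans per run (168 over the session).
#'
#' @param n_runs Number of runs (default 4).
#' @param blocks_per_condition Blocks of each condition per run (default 6).
#' @param scans_per_block Whole-brain images per block (default 7).
#' @param tr Repetition time in seconds (default 3).
#' @param conditions Character vector of condition labels.
#' @param block_order_seed Seed for the per-run randomized block order.
#' @return A `design_spec` list.
#' @examples
#' d <- design_spec()
#' d$run_duration_s # 378
#' @export
design_spec <- function(n_runs = 4, blocks_per_condition = 6,
                        scans_per_block = 7, tr = 3,
                        conditions = c("AP", "IP", "REST"),
                        block_order_seed = 1L) {
  n_runs <- assert_count(n_runs, "n_runs")
  blocks_per_condition <- assert_count(blocks_per_condition,
                                       "blocks_per_condition")
  scans_per_block <- assert_count(scans_per_block, "scans_per_block")
  stopifnot(is.numeric(tr), tr > 0, length(conditions) >= 1,
            !anyDuplicated(conditions))
  spec <- list(
    n_runs = n_runs,
    blocks_per_condition = blocks_per_condition,
    scans_per_block = scans_per_block,
    tr = tr,
    conditions = as.character(conditions),
    block_order_seed = as.integer(block_order_seed)
  )
  spec$scans_per_run <- blocks_per_condition * length(conditions) *
    scans_per_block
  spec$run_duration_s <- spec$scans_per_run * tr
  structure(spec, class = "design_spec")
}

#' Build the scan-by-scan block schedule
#'
#' Expands a [design_spec()] into a scan-level schedule: for each run, the
#' block order is a seeded random permutation of `blocks_per_condition`
#' repetitions of every condition ("randomized across time series"), and each
#' block contributes `scans_per_block` consecutive scans. The schedule is
#' deterministic given `block_order_seed` and balanced by construction:
#' every condition has the same scan count in every run.
#'
#' @param spec A `design_spec`.
#' @return Data frame with columns `run`, `scan` (1-based within run),
#'   `block` (within-run block number), `condition`; rows in run-major
#'   temporal order.
#' @examples
#' sched <- make_design(design_spec())
#' nrow(sched) # 504 scans (4 runs x 126)
#' @export
make_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  rows <- lapply(seq_len(spec$n_runs), function(run) {
    blocks <- rep(spec$conditions, each = spec$blocks_per_condition)
    if (length(blocks) > 1) {
      seed <- derive_seed(spec$block_order_seed, "block-order", run)
      blocks <- withr_seed_sample(blocks, seed)
    }
    data.frame(
      run = run,
      scan = seq_len(spec$scans_per_run),
      block = rep(seq_along(blocks), each = spec$scans_per_block),
      condition = rep(blocks, each = spec$scans_per_block),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# sample() under a local RNG state, leaving the caller's RNG untouched
withr_seed_sample <- function(x, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample(x)
}

#' Sparse partial-correlation precision model
#'
#' Specifies a Gaussian graphical model by its support (the node pairs with
#' nonzero partial correlation) and target partial correlations — the
#' ground-truth object that network inference should recover.
#'
#' @param n_nodes Number of nodes.
#' @param support Integer matrix with two columns (`i`, `j`, 1-based,
#'   `i != j`) of supported pairs, or `NULL` for an empty (diagonal) model.
#' @param target_partial_r Target partial correlation per support pair
#'   (recycled if scalar); each in (-1, 1).
#' @param diagonal Positive precision diagonal (recycled; default 1).
#' @return A `precision_model` list.
#' @export
precision_model <- function(n_nodes, support = NULL, target_partial_r = 0.3,
                            diagonal = 1) {
  n_nodes <- assert_count(n_nodes, "n_nodes")
  if (is.null(support)) {
    support <- matrix(integer(0), ncol = 2)
  }
  support <- as.matrix(support)
  if (ncol(support) != 2) stop("support must have two columns",
                               call. = FALSE)
  if (nrow(support)) {
    if (any(support < 1 | support > n_nodes)) {
      stop("support indices out of range 1..n_nodes", call. = FALSE)
    }
    if (any(support[, 1] == support[, 2])) {
      stop("support may not contain self-pairs", call. = FALSE)
    }
    support <- t(apply(support, 1, sort))
    if (anyDuplicated(support)) stop("duplicate support pairs",
                                     call. = FALSE)
  }
  target_partial_r <- rep_len(target_partial_r, nrow(support))
  if (nrow(support) && any(abs(target_partial_r) >= 1)) {
    stop("target partial correlations must lie in (-1, 1)", call. = FALSE)
  }
  diagonal <- rep_len(diagonal, n_nodes)
  if (any(diagonal <= 0)) stop("precision diagonal must be positive",
                               call. = FALSE)
  structure(list(n_nodes = n_nodes, support = support,
                 target_partial_r = as.numeric(target_partial_r),
                 diagonal = as.numeric(diagonal)),
            class = "precision_model")
}

#' Construct an SPD precision matrix with prescribed partial correlations
#'
#' Builds the precision (inverse covariance) matrix `Omega` implied by a
#' [precision_model()]: in the normalized parameterization
#' `Omega = D^(1/2) (I - s P) D^(1/2)`, where `P` carries the target partial
#' correlations on the support and `D` the requested diagonal, the implied
#' partial correlation `-Omega_ij / sqrt(Omega_ii Omega_jj)` equals
#' `s * target_ij` exactly. Off-support partial correlations are exactly 0.
#'
#' If the exact targets (`s = 1`) already give smallest eigenvalue at or
#' above `eig_floor`, they are kept. Otherwise the off-diagonal scale `s` is
#' reduced by bisection — equivalent to loading the diagonal and rescaling —
#' until the eigenvalue floor holds; the shrunken partial correlations must
#' stay within `tol` (0.02) of their targets, else the model is declared
#' infeasible with an error. Nothing is ever clipped silently.
#'
#' @param model A `precision_model`.
#' @param eig_floor Smallest admissible eigenvalue of the normalized
#'   precision (default 0.05).
#' @param tol Maximum allowed deviation of implied from target partial
#'   correlations (default 0.02).
#' @param max_iter Bisection iteration cap.
#' @return Symmetric positive-definite precision matrix.
#' @examples
#' m <- precision_model(2, rbind(c(1, 2)), 0.5)
#' Om <- build_precision(m)
#' -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2]) # 0.5
#' @export
build_precision <- function(model, eig_floor = 0.05, tol = 0.02,
                            max_iter = 60) {
  stopifnot(inherits(model, "precision_model"))
  n <- model$n_nodes
  P <- matrix(0, n, n)
  if (nrow(model$support)) {
    idx <- cbind(model$support[, 1], model$support[, 2])
    P[idx] <- model$target_partial_r
    P[idx[, c(2, 1), drop = FALSE]] <- model$target_partial_r
  }
  normalized <- function(s) diag(n) - s * P
  min_eig <- function(s) min(eigen(normalized(s), symmetric = TRUE,
                                   only.values = TRUE)$values)
  s <- 1
  if (min_eig(1) < eig_floor) {
    lo <- 0
    hi <- 1
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      if (min_eig(mid) >= eig_floor) lo <- mid else hi <- mid
    }
    s <- lo
    max_dev <- max(abs((1 - s) * model$target_partial_r))
    if (max_dev > tol) {
      stop(sprintf(paste0(
        "infeasible precision model: restoring the eigenvalue floor %.3g ",
        "moves partial correlations up to %.4f away from their targets ",
        "(tolerance %.3g); weaken the targets or thin the support"),
        eig_floor, max_dev, tol), call. = FALSE)
    }
  }
  d <- sqrt(model$diagonal)
  Omega <- outer(d, d) * normalized(s)
  (Omega + t(Omega)) / 2
}

#' Partial correlations implied by a precision matrix
#'
#' Closed form `rho_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)`, with the
#' diagonal set to 0.
#'
#' @param Omega Symmetric positive-definite precision matrix.
#' @return Symmetric partial-correlation matrix, zero diagonal.
#' @export
partial_from_precision <- function(Omega) {
  assert_symmetric(Omega, tol = 1e-8, name = "Omega")
  d <- sqrt(diag(Omega))
  rho <- -Omega / outer(d, d)
  diag(rho) <- 0
  rho
}

# Assign per-edge partial-correlation targets under a per-node budget.
# Capping every node's sum of |target| at `budget` bounds the spectral
# radius of the normalized off-diagonal block (Gershgorin), so the implied
# precision matrix is positive definite by construction for any sign
# pattern. Edges are visited in the given order; an edge receives the
# nominal magnitude truncated to both endpoints' remaining budgets, and is
# dropped when that falls below `r_min`.
allocate_support_targets <- function(n_nodes, pairs, r_mag, signs,
                                     budget = 0.85, r_min = 0.08) {
  remaining <- rep(budget, n_nodes)
  keep <- logical(nrow(pairs))
  r_out <- numeric(nrow(pairs))
  for (e in seq_len(nrow(pairs))) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    r <- min(r_mag, remaining[i], remaining[j])
    if (r >= r_min) {
      keep[e] <- TRUE
      r_out[e] <- r * signs[e]
      remaining[i] <- remaining[i] - r
      remaining[j] <- remaining[j] - r
    }
  }
  list(pairs = pairs[keep, , drop = FALSE], r = r_out[keep])
}

#' Default group-by-condition precision models for a simulated cohort
#'
#' Encodes the generative contrasts of the study design: the older group has
#' denser support and stronger partial correlations than the younger group
#' (`age_density_increment`, `age_r_increment` over the young baseline), and
#' the harder AP condition is denser than IP (`phase_density_increment`).
#' Support pairs are drawn in a shared random order, so the young IP support
#' is (up to budget truncation) nested inside young AP and the old variants.
#' REST uses an empty (diagonal) model.
#'
#' Per-edge magnitudes follow a per-node budget rule: each node can carry at
#' most `budget` total absolute partial correlation, edges receive the
#' nominal group magnitude truncated to the endpoints' remaining budgets,
#' and edges that would fall below `r_min` are dropped. This mirrors how
#' sparse Gaussian graphical models behave — hub nodes divide their shared
#' variance among neighbours — and guarantees a positive-definite precision
#' matrix for any sign pattern, by the Gershgorin bound on the normalized
#' off-diagonal block. Edge signs are drawn mostly positive
#' (`prob_positive`), reflecting the predominantly positive partial
#' correlations of task-coactivated regions.
#'
#' @param n_nodes Number of nodes (21 for the N1 atlas).
#' @param young_density Fraction of node pairs offered to the young IP
#'   model (default 0.20).
#' @param young_r Nominal partial-correlation magnitude for the young group
#'   (default 0.25).
#' @param age_density_increment Extra support density for the old group
#'   (default +0.10).
#' @param age_r_increment Extra partial-correlation magnitude for the old
#'   group (default +0.10).
#' @param phase_density_increment Extra support density for AP over IP
#'   (default +0.05).
#' @param prob_positive Probability an edge's partial correlation is
#'   positive (default 0.8).
#' @param budget Per-node cap on summed absolute partial correlations
#'   (default 0.85).
#' @param r_min Smallest retained edge magnitude (default 0.08).
#' @param seed Seed for support-pair and sign draws.
#' @return Named list `old.AP`, `old.IP`, `old.REST`, `young.AP`, ... of
#'   `precision_model` objects.
#' @export
default_group_models <- function(n_nodes = 21, young_density = 0.20,
                                 young_r = 0.25,
                                 age_density_increment = 0.10,
                                 age_r_increment = 0.10,
                                 phase_density_increment = 0.05,
                                 prob_positive = 0.8, budget = 0.85,
                                 r_min = 0.08, seed = 20130429) {
  n_nodes <- assert_count(n_nodes, "n_nodes")
  all_pairs <- t(utils::combn(n_nodes, 2))
  n_pairs <- nrow(all_pairs)
  n_base <- round(young_density * n_pairs)
  n_phase <- round(phase_density_increment * n_pairs)
  n_age <- round(age_density_increment * n_pairs)
  if (n_base + n_phase + n_age > n_pairs) {
    stop("requested support densities exceed the number of node pairs",
         call. = FALSE)
  }
  ord <- withr_seed_sample(seq_len(n_pairs), derive_seed(seed, "support"))
  base <- ord[seq_len(n_base)]
  phase_extra <- ord[n_base + seq_len(n_phase)]
  age_extra <- ord[n_base + n_phase + seq_len(n_age)]
  signs_all <- local({
    u <- withr_seed_sample(seq_len(n_pairs), derive_seed(seed, "signs"))
    ifelse(u <= round(prob_positive * n_pairs), 1, -1)
  })
  mk <- function(pair_idx, r_mag) {
    alloc <- allocate_support_targets(
      n_nodes, all_pairs[pair_idx, , drop = FALSE], r_mag,
      signs_all[pair_idx], budget = budget, r_min = r_min)
    precision_model(n_nodes, alloc$pairs, alloc$r)
  }
  list(
    old.AP = mk(c(base, phase_extra, age_extra),
                young_r + age_r_increment),
    old.IP = mk(c(base, age_extra), young_r + age_r_increment),
    old.REST = precision_model(n_nodes),
    young.AP = mk(c(base, phase_extra), young_r),
    young.IP = mk(base, young_r),
    young.REST = precision_model(n_nodes)
  )
}

#' Cohort specification for the synthetic study
#'
#' Bundles everything needed to simulate a two-group block-design fMRI
#' cohort: the scanning design, per group-by-condition generative precision
#' models, noise scale, temporal autocorrelation, task-evoked mean shift,
#' and a master seed from which all per-subject streams derive.
#'
#' @param design A [design_spec()].
#' @param n_per_group Subjects per group (default 16, as in the study).
#' @param group_models Named list of `precision_model`s keyed
#'   `"<group>.<condition>"`; default [default_group_models()].
#' @param noise_sd Innovation scale in BOLD arbitrary units (default 1).
#' @param ar1_coefficient AR(1) temporal autocorrelation in `[0, 1)`
#'   (default 0.3, a typical value at TR = 3 s).
#' @param task_amplitude Boxcar mean shift added during task blocks, BOLD
#'   units (default 0.5).
#' @param master_seed Master seed for the cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(design = design_spec(), n_per_group = 16,
                        group_models = NULL, noise_sd = 1,
                        ar1_coefficient = 0.3, task_amplitude = 0.5,
                        master_seed = 1L) {
  stopifnot(inherits(design, "design_spec"))
  n_per_group <- assert_count(n_per_group, "n_per_group")
  stopifnot(noise_sd > 0, ar1_coefficient >= 0, ar1_coefficient < 1)
  if (is.null(group_models)) {
    group_models <- default_group_models(seed = derive_seed(master_seed,
                                                            "models"))
  }
  needed <- as.vector(outer(c("old", "young"),
                            setdiff(design$conditions, character(0)),
                            paste, sep = "."))
  missing_m <- setdiff(needed, names(group_models))
  if (length(missing_m)) {
    stop("group_models is missing: ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  }
  n_nodes <- unique(vapply(group_models, function(m) m$n_nodes, integer(1)))
  if (length(n_nodes) != 1) {
    stop("all group models must share n_nodes", call. = FALSE)
  }
  structure(list(design = design, n_per_group = n_per_group,
                 group_models = group_models, n_nodes = n_nodes,
                 noise_sd = noise_sd, ar1_coefficient = ar1_coefficient,
                 task_amplitude = task_amplitude,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# covariance implied by a group/condition model, cached per call site
cohort_sigma <- function(cohort, group, condition) {
  key <- paste(group, condition, sep = ".")
  Omega <- build_precision(cohort$group_models[[key]])
  solve(Omega) * cohort$noise_sd^2
}

#' Simulate one subject's per-condition ROI time series
#'
#' Draws, for every condition in the design, the ROI x scan matrix of
#' concatenated condition epochs across runs. Scans are sampled from a
#' zero-mean multivariate normal whose covariance is the inverse of the
#' group-and-condition precision model, passed through a
#' variance-preserving AR(1) filter along time (reset at run boundaries),
#' with a boxcar task mean of `task_amplitude` added during task (non-REST)
#' blocks. The per-subject random stream derives deterministically from
#' `master_seed`, group and subject index, so cohorts are reproducible and
#' subjects independent.
#'
#' @param cohort A [cohort_spec()].
#' @param group `"old"` or `"young"`.
#' @param subject_index 1-based subject index within the group.
#' @return Named list (one entry per condition) of
#'   `subject_condition_series` objects: matrices of size
#'   `n_nodes x n_condition_scans` with attributes `subject_id`, `group`,
#'   `condition`, `n_scans`.
#' @export
simulate_subject <- function(cohort, group = c("old", "young"),
                             subject_index) {
  stopifnot(inherits(cohort, "cohort_spec"))
  group <- match.arg(group)
  subject_index <- assert_count(subject_index, "subject_index")
  if (subject_index > cohort$n_per_group) {
    stop("subject_index exceeds n_per_group", call. = FALSE)
  }
  design <- cohort$design
  sched <- make_design(design)
  phi <- cohort$ar1_coefficient
  out <- list()
  for (cond in design$conditions) {
    Sigma <- cohort_sigma(cohort, group, cond)
    L <- t(chol(Sigma))
    n_nodes <- nrow(Sigma)
    seed <- derive_seed(cohort$master_seed, group, subject_index, cond)
    cols_per_run <- sum(sched$condition == cond & sched$run == 1)
    mats <- local({
      old_rs <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        get(".Random.seed", globalenv())
      }
      on.exit({
        if (is.null(old_rs)) {
          if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old_rs, envir = globalenv())
      })
      set.seed(seed)
      lapply(seq_len(design$n_runs), function(run) {
        e <- L %*% matrix(stats::rnorm(n_nodes * cols_per_run),
                          n_nodes, cols_per_run)
        if (phi > 0 && cols_per_run > 1) {
          x <- e
          for (t in 2:cols_per_run) {
            x[, t] <- phi * x[, t - 1] + sqrt(1 - phi^2) * e[, t]
          }
          x
        } else e
      })
    })
    mat <- do.call(cbind, mats)
    if (!identical(cond, "REST")) {
      mat <- mat + cohort$task_amplitude
    }
    labels <- sprintf("node%02d", seq_len(n_nodes))
    rownames(mat) <- labels
    out[[cond]] <- structure(
      mat,
      subject_id = sprintf("%s%02d", group, subject_index),
      group = group, condition = cond, n_scans = ncol(mat),
      class = c("subject_condition_series", "matrix", "array")
    )
  }
  out
}

#' Simulate kinematic outcomes for one subject
#'
#' Draws the two behavioural summary measures of bimanual coordination:
#' mean phase error (degrees, deviation from the 0/180 degree target
#' relative phase) and phase stability (SD of relative phase, degrees). The
#' generative means are condition-specific — the anti-phase (AP) mode is
#' harder, with larger error and SD than in-phase (IP) — and identical
#' across age groups, emulating the per-subject frequency titration that
#' matched old and young performance by design.
#'
#' An optional standardized connectivity summary can be linearly coupled in:
#' with coupling `c`, the standardized deviate is
#' `c * summary + sqrt(1 - c^2) * noise`, so the population correlation
#' between summary and outcome equals `c`.
#'
#' @param cohort A [cohort_spec()].
#' @param group `"old"` or `"young"`.
#' @param subject_index 1-based subject index.
#' @param condition `"AP"` or `"IP"`.
#' @param connectivity_summary Optional standardized (mean 0, SD 1) scalar
#'   summary for this subject.
#' @param coupling Linear coupling in `[-1, 1]` (default 0).
#' @return Named numeric: `phase_error`, `phase_sd` (degrees).
#' @export
simulate_kinematics <- function(cohort, group = c("old", "young"),
                                subject_index, condition = c("AP", "IP"),
                                connectivity_summary = NULL, coupling = 0) {
  stopifnot(inherits(cohort, "cohort_spec"), abs(coupling) <= 1)
  group <- match.arg(group)
  condition <- match.arg(condition)
  subject_index <- assert_count(subject_index, "subject_index")
  # population parameters (degrees): AP harder than IP, groups identical
  params <- list(AP = c(mu_err = 15, sd_err = 4, mu_sd = 18, sd_sd = 4),
                 IP = c(mu_err = 8, sd_err = 3, mu_sd = 10, sd_sd = 3))
  p <- params[[condition]]
  seed <- derive_seed(cohort$master_seed, "kinematics", group,
                      subject_index, condition)
  old_rs <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_rs)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_rs, envir = globalenv())
  })
  set.seed(seed)
  noise <- stats::rnorm(2)
  z <- if (is.null(connectivity_summary) || coupling == 0) {
    noise
  } else {
    coupling * connectivity_summary + sqrt(1 - coupling^2) * noise
  }
  c(phase_error = p[["mu_err"]] + p[["sd_err"]] * z[1],
    phase_sd = p[["mu_sd"]] + p[["sd_sd"]] * z[2])
}

#' Simulate a full cohort
#'
#' Convenience wrapper: all subjects of both groups, all conditions, plus
#' kinematics and the ground-truth support of every generative model.
#'
#' @param cohort A [cohort_spec()].
#' @param conditions Conditions to keep (default `c("AP", "IP")`, the task
#'   conditions entering connectivity analysis).
#' @return List with elements `series` (named
#'   `series[[group]][[subject]][[condition]]`), `kinematics` (data frame),
#'   and `truth` (list of support matrices per group-condition model).
#' @export
simulate_cohort <- function(cohort, conditions = c("AP", "IP")) {
  stopifnot(inherits(cohort, "cohort_spec"))
  series <- list()
  kin <- list()
  for (group in c("old", "young")) {
    series[[group]] <- vector("list", cohort$n_per_group)
    for (s in seq_len(cohort$n_per_group)) {
      subj <- simulate_subject(cohort, group, s)
      series[[group]][[s]] <- subj[conditions]
      for (cond in intersect(conditions, c("AP", "IP"))) {
        k <- simulate_kinematics(cohort, group, s, cond)
        kin[[length(kin) + 1]] <- data.frame(
          subject_id = sprintf("%s%02d", group, s), group = group,
          condition = cond, phase_error = k[["phase_error"]],
          phase_sd = k[["phase_sd"]], stringsAsFactors = FALSE)
      }
    }
  }
  truth <- lapply(cohort$group_models, function(m) {
    list(support = m$support, target_partial_r = m$target_partial_r)
  })
  list(series = series, kinematics = do.call(rbind, kin), truth = truth)
}

#' Write a simulated cohort to disk
#'
#' One tab-separated ROI x scan matrix per subject-condition (node labels as
#' header) plus a JSON manifest recording the design, seeds, and the
#' ground-truth support of every generative model.
#'
#' @param cohort A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @param conditions Conditions to write (default task conditions).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir, conditions = c("AP", "IP")) {
  sim <- simulate_cohort(cohort, conditions)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (group in names(sim$series)) {
    for (s in seq_along(sim$series[[group]])) {
      for (cond in conditions) {
        mat <- sim$series[[group]][[s]][[cond]]
        fn <- file.path(dir, sprintf("%s%02d_%s.tsv", group, s, cond))
        utils::write.table(t(unclass(mat)), fn, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
    }
  }
  utils::write.table(sim$kinematics, file.path(dir, "kinematics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    design = unclass(cohort$design),
    n_per_group = cohort$n_per_group,
    noise_sd = cohort$noise_sd,
    ar1_coefficient = cohort$ar1_coefficient,
    task_amplitude = cohort$task_amplitude,
    master_seed = cohort$master_seed,
    truth = sim$truth
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
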