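test_that("block design arithmetic matches the scanning protocol", {
  d <- design_spec()
  expect_equal(d$run_duration_s, 378)
  expect_equal(d$scans_per_run, 126)
  sched <- make_design(d)
  expect_equal(nrow(sched), 4 * 126)
  # per-run balance: 42 scans of each condition, 168 over the session
  per_run <- table(sched$run, sched$condition)
  expect_true(all(per_run == 42))
  expect_equal(sum(sched$condition == "AP"), 168)
  # deterministic given the block-order seed
  expect_identical(make_design(d), make_design(design_spec()))
  d2 <- design_spec(block_order_seed = 99)
  expect_false(identical(make_design(d)$condition,
                         make_design(d2)$condition))
  # degenerate single-block design
  tiny <- design_spec(n_runs = 1, blocks_per_condition = 1,
                      scans_per_block = 1, conditions = "AP")
  expect_equal(nrow(make_design(tiny)), 1)
})

test_that("build_precision hits targets exactly when feasible", {
  # empty support: diagonal matrix, all partial correlations zero
  Om <- build_precision(precision_model(4, diagonal = c(1, 2, 3, 4)))
  expect_equal(Om, diag(c(1, 2, 3, 4)))
  expect_true(all(partial_from_precision(Om) == 0))
  # 2-node closed form: rho = -Omega12 / sqrt(Omega11 * Omega22)
  Om2 <- build_precision(precision_model(2, rbind(c(1, 2)), 0.5))
  expect_equal(-Om2[1, 2] / sqrt(Om2[1, 1] * Om2[2, 2]), 0.5)
  # random sparse 10-node model: inversion oracle recovers the targets
  set.seed(7)
  pairs <- t(utils::combn(10, 2))
  pick <- sample(nrow(pairs), 9)
  r <- round(stats::runif(9, -0.3, 0.3), 2)
  m <- precision_model(10, pairs[pick, ], r)
  Om10 <- build_precision(m)
  expect_gt(min(eigen(Om10, only.values = TRUE)$values), 0)
  rho <- partial_from_precision(Om10)
  expect_equal(rho[m$support], m$target_partial_r, tolerance = 0.02)
  off <- matrix(TRUE, 10, 10)
  off[m$support] <- FALSE
  off[m$support[, c(2, 1)]] <- FALSE
  diag(off) <- FALSE
  expect_true(all(rho[off] == 0))
})

test_that("infeasible precision targets raise an explicit error", {
  # a triangle of partial correlations 0.9 cannot be positive definite
  tri <- precision_model(3, rbind(c(1, 2), c(1, 3), c(2, 3)), 0.9)
  expect_error(build_precision(tri), "infeasible")
  expect_error(precision_model(3, rbind(c(1, 1)), 0.2), "self-pairs")
  expect_error(precision_model(3, rbind(c(1, 4)), 0.2), "out of range")
})

test_that("default group models are feasible and express the age contrast", {
  gm <- default_group_models()
  for (m in gm) {
    Om <- build_precision(m)
    expect_gt(min(eigen(Om, only.values = TRUE)$values), 0)
    expect_no_error(chol(solve(Om)))
  }
  mean_r <- function(m) if (nrow(m$support)) mean(abs(m$target_partial_r)) else 0
  expect_gt(mean_r(gm$old.AP), mean_r(gm$young.AP))
  expect_gt(mean_r(gm$old.IP), mean_r(gm$young.IP))
  expect_equal(nrow(gm$old.REST$support), 0)
})

test_that("simulated series have the design's epoch counts and are reproducible", {
  cs <- cohort_spec(n_per_group = 2, master_seed = 5)
  subj <- simulate_subject(cs, "old", 1)
  expect_equal(ncol(subj$AP), 168)
  expect_equal(ncol(subj$IP), 168)
  expect_equal(nrow(subj$AP), 21)
  expect_identical(attr(subj$AP, "condition"), "AP")
  # determinism: same seed gives bitwise-identical output
  again <- simulate_subject(cs, "old", 1)
  expect_identical(subj, again)
  # different subjects get different draws
  other <- simulate_subject(cs, "old", 2)
  expect_false(identical(unclass(subj$AP), unclass(other$AP)))
  expect_error(simulate_subject(cs, "old", 3), "exceeds n_per_group")
})

test_that("independence limit: identity precision yields near-zero partials", {
  n_nodes <- 6
  ident <- stats::setNames(
    rep(list(precision_model(n_nodes)), 6),
    as.vector(outer(c("old", "young"), c("AP", "IP", "REST"), paste,
                    sep = ".")))
  big_design <- design_spec(n_runs = 1, blocks_per_condition = 1429,
                            scans_per_block = 7)
  cs <- cohort_spec(design = big_design, n_per_group = 1,
                    group_models = ident, ar1_coefficient = 0,
                    task_amplitude = 0, master_seed = 3)
  x <- simulate_subject(cs, "young", 1)$AP
  expect_gte(ncol(x), 10000)
  rho <- partial_correlation(x)$values
  expect_lt(max(abs(rho)), 0.1)
})

test_that("ground-truth support is recovered at deep sampling", {
  # chain model with |r| = 0.3: at 10,000 scans and alpha 0.001 the
  # thresholded edge set equals the true support exactly
  n_nodes <- 10
  chain <- cbind(1:9, 2:10)
  r <- 0.3 * rep(c(1, -1), length.out = 9)
  models <- stats::setNames(
    rep(list(precision_model(n_nodes, chain, r)), 6),
    as.vector(outer(c("old", "young"), c("AP", "IP", "REST"), paste,
                    sep = ".")))
  big_design <- design_spec(n_runs = 1, blocks_per_condition = 1429,
                            scans_per_block = 7)
  cs <- cohort_spec(design = big_design, n_per_group = 1,
                    group_models = models, ar1_coefficient = 0,
                    master_seed = 17)
  x <- simulate_subject(cs, "old", 1)$AP
  g <- threshold_network(partial_correlation(x), 0.001)
  found <- which(upper.tri(g$binary) & g$binary == 1, arr.ind = TRUE)
  expect_equal(unname(found[order(found[, 1], found[, 2]), , drop = FALSE]),
               unname(chain))
})

test_that("kinematics emulate matched groups and the AP difficulty penalty", {
  big <- cohort_spec(n_per_group = 10000, master_seed = 9)
  draw <- function(group, cond, n) {
    t(vapply(seq_len(n), function(s) {
      simulate_kinematics(big, group, s, cond)
    }, numeric(2)))
  }
  n_draw <- 10000
  old_ap <- draw("old", "AP", n_draw)
  young_ap <- draw("young", "AP", n_draw)
  old_ip <- draw("old", "IP", n_draw)
  # groups share generative parameters: mean difference < 0.5 degrees
  expect_lt(abs(mean(old_ap[, 1]) - mean(young_ap[, 1])), 0.5)
  expect_lt(abs(mean(old_ap[, 2]) - mean(young_ap[, 2])), 0.5)
  # AP is harder than IP for both measures
  expect_gt(mean(old_ap[, 1]), mean(old_ip[, 1]))
  expect_gt(mean(old_ap[, 2]), mean(old_ip[, 2]))
  # full coupling to an injected standardized summary gives R near 1
  set.seed(2)
  z <- stats::rnorm(1000)
  err <- vapply(seq_along(z), function(s) {
    simulate_kinematics(big, "old", s, "AP", connectivity_summary = z[s],
                        coupling = 1)[["phase_error"]]
  }, numeric(1))
  expect_gt(stats::cor(z, err), 0.9)
})

test_that("cohort export writes matrices and a ground-truth manifest", {
  cs <- cohort_spec(
    n_per_group = 2,
    group_models = default_group_models(n_nodes = 6, seed = 4),
    master_seed = 21)
  dir <- tempfile("cohort")
  manifest_path <- write_cohort(cs, dir)
  expect_true(file.exists(file.path(dir, "old01_AP.tsv")))
  expect_true(file.exists(file.path(dir, "young02_IP.tsv")))
  expect_true(file.exists(file.path(dir, "kinematics.tsv")))
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  expect_equal(man$n_per_group, 2)
  expect_equal(man$design$run_duration_s, 378)
  expect_true("old.AP" %in% names(man$truth))
  # round trip: the written matrix equals the simulated one
  sim <- simulate_cohort(cs)
  back <- t(as.matrix(utils::read.delim(file.path(dir, "old01_AP.tsv"),
                                        check.names = FALSE)))
  expect_equal(unname(back), unname(unclass(sim$series$old[[1]]$AP)),
               tolerance = 1e-12, ignore_attr = TRUE)
})
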