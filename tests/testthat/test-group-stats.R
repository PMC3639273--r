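test_that("degenerate ANOVA inputs are flagged, not hidden", {
  rec <- make_records(rep(3, 16), n_per_group = 4)
  fit <- mixed_anova(rec)
  expect_equal(fit$F, c(0, 0, 0))
  expect_equal(fit$p, c(1, 1, 1))
  # pure additive group shift with zero noise: infinite AGE F
  rec2 <- make_records(ifelse(make_records(0, 4)$group == "old", 1, 0), 4)
  fit2 <- mixed_anova(rec2)
  expect_equal(fit2$F[fit2$effect == "AGE"], Inf)
  expect_equal(fit2$p[fit2$effect == "AGE"], 0)
  expect_equal(fit2$F[fit2$effect == "PHASE"], 0)
  expect_equal(fit2$F[fit2$effect == "AGE:PHASE"], 0)
  # incomplete within-subject data is an error naming the subject
  rec3 <- make_records(rnorm(16), 4)[-1, ]
  expect_error(mixed_anova(rec3), "s01")
})

test_that("split-plot F values match a hand-computed integer fixture", {
  # 4 subjects per group, integer values; sums of squares done by hand:
  # cells (old AP, old IP, young AP, young IP) = (6, 4, 3, 3) + subject
  # offsets (-1, 0, 1, 2) within each group, identical across conditions.
  old_ap <- c(5, 6, 7, 8); old_ip <- c(3, 4, 5, 6)
  young_ap <- c(2, 3, 4, 5); young_ip <- c(2, 3, 4, 5)
  rec <- data.frame(
    subject_id = rep(sprintf("s%02d", 1:8), 2),
    group = rep(rep(c("old", "young"), each = 4), 2),
    condition = rep(c("AP", "IP"), each = 8),
    value = c(old_ap, young_ap, old_ip, young_ip),
    stringsAsFactors = FALSE)
  fit <- mixed_anova(rec)
  # grand mean 4.5; group means old 5.5, young 3.5 -> SS_AGE = 8*2 = 16
  # subject means deviate (-1.5,-0.5,0.5,1.5) within each group ->
  # SS_subjects-within-groups = 2*(5+5) = 20 -> MS_subj = 20/6
  # condition means 5 / 4 -> SS_PHASE = 8*(0.25+0.25) = 4
  # cell interaction deviations all +/-0.5 -> SS_INT = 4*1 = 4
  # residual within error: 0 -> PHASE and AGE:PHASE F infinite
  expect_equal(fit$F[fit$effect == "AGE"], 16 / (20 / 6))
  expect_equal(fit$df_den[fit$effect == "AGE"], 6)
  expect_equal(fit$F[fit$effect == "PHASE"], Inf)
  expect_equal(fit$F[fit$effect == "AGE:PHASE"], Inf)
  ss <- attr(fit, "ss")
  expect_equal(unname(ss["age"]), 16)
  expect_equal(unname(ss["phase"]), 4)
  expect_equal(unname(ss["interaction"]), 4)
})

test_that("mixed ANOVA agrees with the aov split-plot oracle", {
  set.seed(41)
  for (rep in 1:5) {
    rec <- make_records(rnorm(32, sd = 2) +
                          rep(rnorm(16), 2), n_per_group = 8)
    rec$value <- rec$value + ifelse(rec$group == "old", 0.8, 0) +
      ifelse(rec$condition == "AP", 0.5, 0)
    fit <- mixed_anova(rec)
    oracle <- summary(stats::aov(
      value ~ group * condition + Error(subject_id),
      data = transform(rec, group = factor(group),
                       condition = factor(condition))))
    between <- oracle[["Error: subject_id"]][[1]]
    within <- oracle[["Error: Within"]][[1]]
    pick <- function(tab, term, col) {
      tab[which(trimws(rownames(tab)) == term), col]
    }
    expect_equal(fit$F[fit$effect == "AGE"],
                 pick(between, "group", "F value"), tolerance = 1e-10)
    expect_equal(fit$p[fit$effect == "AGE"],
                 pick(between, "group", "Pr(>F)"), tolerance = 1e-10)
    expect_equal(fit$F[fit$effect == "PHASE"],
                 pick(within, "condition", "F value"), tolerance = 1e-10)
    expect_equal(fit$F[fit$effect == "AGE:PHASE"],
                 pick(within, "group:condition", "F value"),
                 tolerance = 1e-10)
    expect_equal(fit$df_den, c(14, 14, 14))
  }
})

test_that("ANOVA sums of squares decompose the total exactly", {
  set.seed(42)
  for (rep in 1:10) {
    rec <- make_records(rnorm(48), n_per_group = 12)
    fit <- mixed_anova(rec)
    ss <- attr(fit, "ss")
    parts <- ss["age"] + ss["subjects_within_groups"] + ss["phase"] +
      ss["interaction"] + ss["error_within"]
    expect_equal(unname(parts), unname(ss["total"]), tolerance = 1e-10)
  }
})

test_that("AGE F equals the squared two-sample t on subject means", {
  set.seed(43)
  rec <- make_records(rnorm(64), n_per_group = 16)
  fit <- mixed_anova(rec)
  sm <- tapply(rec$value, rec$subject_id, mean)
  grp <- tapply(rec$group, rec$subject_id, unique)[names(sm)]
  tt <- stats::t.test(sm[grp == "old"], sm[grp == "young"],
                      var.equal = TRUE)
  expect_equal(fit$F[fit$effect == "AGE"], unname(tt$statistic)^2,
               tolerance = 1e-10)
})

test_that("type-I error of each effect is calibrated at the nominal level", {
  set.seed(44)
  n_rep <- 1500
  hits <- matrix(0, n_rep, 3)
  for (b in seq_len(n_rep)) {
    rec <- make_records(rnorm(64), n_per_group = 16)
    hits[b, ] <- mixed_anova(rec)$p < 0.05
  }
  rates <- colMeans(hits)
  for (r in rates) expect_lt(abs(r - 0.05), 0.02)
})

test_that("interhemispheric strength averages only crossing valid edges", {
  tab <- tmp_node_table(c("L", "L", "R"))
  A <- matrix(0, 3, 3)
  A[1, 3] <- A[3, 1] <- 1
  W <- A * 0.62
  expect_equal(interhemispheric_strength(graph_from_adj(A, W), tab), 0.62)
  # only a within-hemisphere edge: missing, never zero
  B <- matrix(0, 3, 3)
  B[1, 2] <- B[2, 1] <- 1
  expect_true(is.na(interhemispheric_strength(graph_from_adj(B), tab)))
  # brute force on a random weighted graph
  set.seed(45)
  hemi <- sample(c("L", "R"), 9, replace = TRUE, prob = c(0.5, 0.5))
  tab9 <- tmp_node_table(hemi)
  A9 <- rand_adj(9, 0.5)
  W9 <- A9 * matrix(runif(81, -1, 1), 9)
  W9 <- (W9 + t(W9)) / 2 * A9
  g9 <- graph_from_adj(A9, W9)
  cross <- outer(hemi, hemi, `!=`) & upper.tri(A9) & A9 == 1
  want <- if (any(cross)) mean(W9[cross]) else NA_real_
  expect_equal(interhemispheric_strength(g9, tab9), want)
})

test_that("Tukey post hoc ranks and bounds comparisons sensibly", {
  set.seed(46)
  base <- rnorm(32, sd = 0.5)
  rec <- make_records(base, n_per_group = 8)
  tk0 <- tukey_posthoc(rec)
  expect_equal(nrow(tk0), 6)
  expect_true(all(tk0$p_adj > 0.05)) # no true effects
  # inject one extreme cell: comparisons involving it get the smallest p
  rec2 <- rec
  boost <- rec2$group == "old" & rec2$condition == "AP"
  rec2$value[boost] <- rec2$value[boost] + 5
  tk2 <- tukey_posthoc(rec2)
  involves <- tk2$cell_a == "old.AP" | tk2$cell_b == "old.AP"
  expect_lt(max(tk2$p_adj[involves]), min(tk2$p_adj[!involves]))
  # identical duplicated records: within-group q = 0 -> p = 1
  rec3 <- make_records(rep(rep(1:16, 2)), n_per_group = 8)
  tk3 <- tukey_posthoc(rec3)
  within_rows <- tk3$stratum == "within"
  expect_true(all(tk3$p_adj[within_rows] > 0.999))
})

test_that("Tukey-adjusted p matches a Monte-Carlo studentized-range null", {
  # homogeneous null (no subject effect): simulate the distribution of the
  # within-group studentized range and compare its exceedance probability
  # at the observed q with the reported adjusted p
  set.seed(47)
  n <- 8
  rec <- make_records(rnorm(4 * n), n_per_group = n)
  tk <- tukey_posthoc(rec)
  row <- which(tk$stratum == "within")[1]
  q_obs <- tk$q[row]
  n_sim <- 4000
  q_null <- replicate(n_sim, {
    sim <- make_records(rnorm(4 * n), n_per_group = n)
    f <- mixed_anova(sim)
    cells <- attr(f, "cell_means")
    ms_w <- attr(f, "ss")[["error_within"]] / (2 * (n - 1))
    (max(cells) - min(cells)) / sqrt(ms_w / n)
  })
  p_mc <- mean(q_null >= q_obs)
  expect_lt(abs(p_mc - tk$p_adj[row]),
            0.06 + 3 * sqrt(p_mc * (1 - p_mc) / n_sim))
})

test_that("kinematics correlations flag at the stated level", {
  # perfect linear relation: R = 1, p ~ 0, flagged
  metrics <- data.frame(subject_id = sprintf("s%02d", 1:16), group = "old",
                        condition = "AP", measure = "degree",
                        value = 1:16, stringsAsFactors = FALSE)
  kin <- data.frame(subject_id = sprintf("s%02d", 1:16), group = "old",
                    condition = "AP", phase_error = 1:16 * 2 + 3,
                    stringsAsFactors = FALSE)
  res <- kinematics_correlations(metrics, kin)
  expect_equal(res$R, 1, tolerance = 1e-12)
  expect_true(res$significant)
  # zero variance: missing R with a recorded reason
  kin2 <- kin
  kin2$phase_error <- 5
  res2 <- kinematics_correlations(metrics, kin2)
  expect_true(is.na(res2$R))
  expect_match(res2$note, "zero variance")
  # null flag rate near the nominal 0.01
  set.seed(48)
  n_rep <- 2000
  flags <- replicate(n_rep, {
    m <- metrics
    m$value <- rnorm(16)
    k <- kin
    k$phase_error <- rnorm(16)
    kinematics_correlations(m, k)$significant
  })
  expect_lt(abs(mean(flags) - 0.01), 0.0075)
})

test_that("coupled kinematics recover the coupling sign", {
  set.seed(49)
  ident <- stats::setNames(
    rep(list(precision_model(2)), 6),
    as.vector(outer(c("old", "young"), c("AP", "IP", "REST"), paste,
                    sep = ".")))
  n_cohort <- 300
  sign_hits <- vapply(seq_len(n_cohort), function(b) {
    spec <- cohort_spec(n_per_group = 16, group_models = ident,
                        master_seed = b)
    z <- rnorm(16)
    err <- vapply(1:16, function(s) {
      simulate_kinematics(spec, "old", s, "AP",
                          connectivity_summary = z[s],
                          coupling = 0.8)[["phase_error"]]
    }, numeric(1))
    stats::cor(z, err) > 0
  }, logical(1))
  expect_gte(mean(sign_hits), 0.95)
})
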