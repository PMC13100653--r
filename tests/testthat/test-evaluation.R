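make_sessions <- function(n_pat = 10, per = 9) {
  data.frame(patient_id = rep(sprintf("p%02d", 1:n_pat), each = per),
             session_id = sprintf("p%02d-s%d",
                                  rep(1:n_pat, each = per), 1:per),
             session_order = rep(1:per, n_pat),
             duration_min = 240)
}

test_that("patient-wise split never splits a patient", {
  ses <- make_sessions()
  sp <- split_sessions(ses, mode = "patient", fraction = 0.7, seed = 4)
  tr_pat <- unique(ses$patient_id[ses$session_id %in% sp$train])
  te_pat <- unique(ses$patient_id[ses$session_id %in% sp$test])
  expect_length(intersect(tr_pat, te_pat), 0)
  expect_setequal(c(sp$train, sp$test), ses$session_id)
})

test_that("session-wise split holds out each patient's latest sessions", {
  ses <- make_sessions(n_pat = 3, per = 9)
  sp <- split_sessions(ses, mode = "session", fraction = 0.7)
  for (p in unique(ses$patient_id)) {
    s <- ses[ses$patient_id == p, ]
    expect_setequal(intersect(sp$train, s$session_id),
                    s$session_id[s$session_order <= 7])  # ceiling(0.7 * 9)
    expect_setequal(intersect(sp$test, s$session_id),
                    s$session_id[s$session_order > 7])
  }
  # every test session is later than every same-patient train session
  ord <- setNames(ses$session_order, ses$session_id)
  pat <- setNames(ses$patient_id, ses$session_id)
  for (ts in sp$test) {
    same <- sp$train[pat[sp$train] == pat[ts]]
    expect_true(all(ord[ts] > ord[same]))
  }
  # single-session patients stay in training
  ses1 <- rbind(make_sessions(2, 9),
                data.frame(patient_id = "solo", session_id = "solo-s1",
                           session_order = 1, duration_min = 240))
  sp1 <- split_sessions(ses1, mode = "session")
  expect_true("solo-s1" %in% sp1$train)
  expect_error(split_sessions(ses, fraction = 1.0), "between 0 and 1")
})

test_that("AUC equals concordant-pair counting and is rank-invariant", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(0:1, 5)), 0.5)
  expect_true(is.na(roc_auc(runif(5), rep(1, 5))))
  set.seed(19)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    s <- round(runif(n), 2)          # duplicates exercise tie handling
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l), auc_brute(s, l))
    expect_equal(roc_auc(exp(3 * s), l), roc_auc(s, l))  # monotone transform
  }
})

test_that("operating point reproduces its 2x2 table metrics", {
  # two candidate thresholds; the optimum (0.8) yields TP 37, FN 13,
  # TN 75, FP 25
  scores <- c(rep(0.8, 37), rep(0.1, 13), rep(0.1, 75), rep(0.8, 25))
  labels <- c(rep(1, 37), rep(1, 13), rep(0, 75), rep(0, 25))
  op <- operating_point(scores, labels)
  expect_equal(op$sensitivity, 0.74)
  expect_equal(op$specificity, 0.75)
  expect_equal(op$npv, 75 / 88)
  expect_equal(op$ppv, 37 / 62)
  expect_equal(unname(op$confusion), c(37, 25, 75, 13))
  # degenerate: all predictions positive at the single candidate threshold
  op2 <- operating_point(rep(0.9, 6), c(1, 1, 1, 0, 0, 1))
  expect_equal(op2$sensitivity, 1)
  expect_equal(op2$specificity, 0)
})

test_that("the returned threshold maximizes Youden over all candidates", {
  set.seed(20)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    s <- round(runif(n), 2)
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    op <- operating_point(s, l)
    for (thr in unique(s)) {
      pred <- as.integer(s >= thr)
      J <- mean(pred[l == 1] == 1) + mean(pred[l == 0] == 0) - 1
      expect_lte(J, op$youden + 1e-12)
    }
  }
})

test_that("Fisher and Wilcoxon comparisons match their oracles", {
  tab <- matrix(c(1, 9, 11, 3), nrow = 2, byrow = TRUE)
  expect_equal(fisher.test(tab)$p.value, fisher_brute(tab),
               tolerance = 1e-10)
  expect_equal(fisher_brute(tab), 0.0027594562, tolerance = 1e-7)
  rows <- data.frame(
    patient_id = "p", session_id = rep(c("a", "b"), each = 10),
    t_min = rep(seq(30, 300, 30), 2),
    rbv_pct = c(seq(99, 90, length.out = 10), seq(98, 89, length.out = 10)),
    label = rep(0:1, 10))
  d <- descriptive_suite(rows)
  w <- suppressWarnings(wilcox.test(rbv_pct ~ label, rows, exact = FALSE))
  expect_equal(d$wilcoxon$p, w$p.value)
  # identical samples give p = 1
  rows2 <- rows
  rows2$rbv_pct <- rep(c(95, 96), 10)
  rows2$label <- rep(0:1, each = 10)
  rows2$rbv_pct <- rep(95, 20)
  expect_equal(descriptive_suite(rows2)$wilcoxon$p, 1)
  # a zero-event bin against a zero-event reference: p = 1
  rows3 <- data.frame(patient_id = "p", session_id = "s",
                      t_min = seq(30, 30 * 8, 30),
                      rbv_pct = c(96, 97, 98, 99, 87, 88, 89, 86),
                      label = 0)
  rows3$label[1] <- 1  # keep the outcome non-constant overall
  d3 <- descriptive_suite(rows3)
  p_8590 <- d3$rbv_bins$p_vs_ref[d3$rbv_bins$bin == "85-90"]
  expect_equal(p_8590, fisher_brute(matrix(c(0, 4, 1, 3), 2, byrow = TRUE)))
})

test_that("RBV bins are left-closed five-point categories", {
  rows <- data.frame(patient_id = "p", session_id = "s",
                     t_min = seq(30, 180, 30),
                     rbv_pct = c(95, 94.99, 90, 85, 80, 79.9),
                     label = c(0, 0, 0, 1, 1, 1))
  b <- descriptive_suite(rows)$rbv_bins
  expect_equal(b$n[b$bin == ">=95"], 1)
  expect_equal(b$n[b$bin == "90-95"], 2)
  expect_equal(b$n[b$bin == "85-90"], 1)
  expect_equal(b$n[b$bin == "80-85"], 1)
  expect_equal(b$n[b$bin == "<80"], 1)
})

test_that("cumulative per-interval comparison separates risk groups", {
  eff <- effect_spec("archetype", intercept = -2.2,
                     terms = c(risk_group = log(6)), sigma_b = 0.5)
  co <- generate_cohort(cohort_config(n_patients = 30,
                                      sessions_per_patient = 5), eff,
                        seed = 78)
  rows <- build_rows(co, mode = "concurrent")
  rg <- setNames(ifelse(co$truth$arch_high, "high", "low"),
                 co$truth$session_id)
  d <- descriptive_suite(rows, risk_groups = rg)
  iv <- d$interval_fisher
  expect_true(all(iv$cum_idh_high >= 0 & iv$cum_idh_high <= 1))
  expect_true(all(diff(iv$cum_idh_high) >= 0))  # cumulative by construction
  # with a 6-fold injected odds ratio the late-session comparison separates
  expect_lt(iv$p[nrow(iv)], 0.05)
  expect_gt(iv$cum_idh_high[nrow(iv)], iv$cum_idh_low[nrow(iv)])
})

test_that("evaluate_model produces coherent split reports", {
  eff <- tiny_continuous_effect(intercept = -2.5, sigma_b = 1.2, or = 1.10)
  co <- generate_cohort(cohort_config(n_patients = 24,
                                      sessions_per_patient = 6), eff,
                        seed = 79)
  rows <- build_rows(co, mode = "horizon")
  rep_s <- evaluate_model(rows, co$sessions, label ~ delta_rbv,
                          mode = "session")
  expect_true(rep_s$auc_test > 0.5 && rep_s$auc_test <= 1)
  expect_equal(rep_s$n$train_rows + rep_s$n$test_rows, nrow(rows))
  op <- rep_s$operating
  expect_equal(sum(op$confusion), rep_s$n$test_rows)
  rep_p <- evaluate_model(rows, co$sessions, label ~ delta_rbv,
                          mode = "patient")
  expect_false(rep_p$split$use_random_effects)
})
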