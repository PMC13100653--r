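test_that("with no heterogeneity the GLMM collapses to plain logistic", {
  eff <- tiny_continuous_effect(intercept = -2, sigma_b = 0, or = 1.08)
  co <- generate_cohort(cohort_config(n_patients = 30,
                                      sessions_per_patient = 5), eff,
                        seed = 71)
  r <- build_rows(co, mode = "concurrent")
  fit <- fit_mixed_logistic(r, label ~ delta_rbv)
  ref <- glm(label ~ delta_rbv, data = r, family = binomial())
  expect_lt(max(abs(fit$coef - coef(ref))), 1e-3)
  expect_lt(fit$sigma_b, 0.05)
})

test_that("binary-covariate OR equals the contingency-table cross product", {
  set.seed(72)
  n <- 400
  rows <- data.frame(patient_id = sprintf("p%03d", seq_len(n)),
                     x = rep(0:1, each = n / 2))
  p <- ifelse(rows$x == 1, 0.35, 0.15)
  rows$label <- rbinom(n, 1, p)
  fit <- fit_mixed_logistic(rows, label ~ x)
  tab <- table(rows$x, rows$label)
  cross_or <- (tab["1", "1"] * tab["0", "0"]) /
    (tab["1", "0"] * tab["0", "1"])
  # pooled data: sigma_b collapses and exp(beta) is the sample odds ratio
  expect_equal(unname(fit$or["x"]), cross_or, tolerance = 1e-3)
})

test_that("fitted likelihood beats the generating parameters' likelihood", {
  eff <- tiny_continuous_effect(intercept = -2.2, sigma_b = 1.2, or = 1.07)
  co <- generate_cohort(tiny_config(), eff, seed = 73)
  r <- build_rows(co, mode = "concurrent")
  fit <- fit_mixed_logistic(r, label ~ delta_rbv)
  X <- cbind(1, r$delta_rbv)
  ll_hat <- glmm_loglik_brute(unname(fit$coef), fit$sigma_b, X, r$label,
                              r$patient_id)
  ll_true <- glmm_loglik_brute(c(eff$intercept, eff$terms[["delta_rbv"]]),
                               eff$sigma_b, X, r$label, r$patient_id)
  expect_gte(ll_hat, ll_true)
  # and the wrapper's reported log-likelihood matches the independent
  # quadrature evaluation at the fitted parameters
  expect_equal(fit$loglik, ll_hat, tolerance = 1e-3)
})

test_that("quadrature is converged at the default node count", {
  eff <- tiny_continuous_effect(intercept = -2.2, sigma_b = 1.2, or = 1.07)
  co <- generate_cohort(tiny_config(), eff, seed = 74)
  r <- build_rows(co, mode = "concurrent")
  f21 <- fit_mixed_logistic(r, label ~ delta_rbv, quad_points = 21)
  f41 <- fit_mixed_logistic(r, label ~ delta_rbv, quad_points = 41)
  expect_lt(max(abs(f21$coef - f41$coef)), 1e-4)
  f1 <- fit_mixed_logistic(r, label ~ delta_rbv, quad_points = 1)  # Laplace
  expect_lt(max(abs(f21$coef - f1$coef)), 0.05)
})

test_that("degenerate inputs raise informative errors", {
  rows <- data.frame(patient_id = rep(c("a", "b"), each = 10),
                     x = rnorm(20), label = 0)
  expect_error(fit_mixed_logistic(rows, label ~ x), "constant")
  rows$label <- as.integer(rows$x > 0)  # perfectly separated
  expect_error(fit_mixed_logistic(rows, label ~ x), "separation")
  one <- data.frame(patient_id = "a", x = rnorm(10),
                    label = rep(0:1, 5))
  expect_error(fit_mixed_logistic(one, label ~ x), "2 patients")
})

test_that("prediction adds exactly the patient posterior mode when asked", {
  eff <- tiny_continuous_effect()
  co <- generate_cohort(tiny_config(), eff, seed = 75)
  r <- build_rows(co, mode = "concurrent")
  fit <- fit_mixed_logistic(r, label ~ delta_rbv)
  p_fix <- predict(fit, r, use_random_effects = FALSE)
  p_re <- predict(fit, r, use_random_effects = TRUE)
  gap <- qlogis(p_re) - qlogis(p_fix)
  expect_equal(unname(gap), unname(fit$ranef[as.character(r$patient_id)]),
               tolerance = 1e-10)
  # unseen patients silently fall back to fixed effects
  r_new <- r[1:5, ]
  r_new$patient_id <- "unseen"
  expect_equal(predict(fit, r_new, use_random_effects = TRUE),
               predict(fit, r_new, use_random_effects = FALSE))
  # monotonicity in a positive-coefficient feature
  r_hi <- r[1:5, ]; r_hi$delta_rbv <- r_hi$delta_rbv + 5
  expect_true(all(predict(fit, r_hi) > predict(fit, r[1:5, ])))
  expect_true(all(p_fix > 0 & p_fix < 1))
})

test_that("association suite recovers injected effects at reduced scale", {
  eff <- effect_spec("threshold", intercept = -2.6,
                     terms = c(below_threshold = log(2.4)), sigma_b = 1,
                     threshold_knots = data.frame(t = c(0, 240),
                                                  tau = c(96, 88)))
  cfg <- cohort_config(n_patients = 40, sessions_per_patient = 6)
  co <- generate_cohort(cfg, eff, seed = 76)
  curve <- generator_threshold_curve(eff)
  rows <- build_rows(co, mode = "concurrent", threshold_curve = curve)
  rg <- setNames(ifelse(co$truth$arch_high, "high", "low"),
                 co$truth$session_id)
  fits <- fit_association_suite(rows, risk_groups = rg)
  expect_setequal(fits$summary$model,
                  c("delta_rbv", "risk_group", "below_threshold"))
  bt <- fits$below_threshold
  expect_lt(abs(bt$coef["below_threshold"] - log(2.4)),
            2.5 * bt$se["below_threshold"])
  expect_true(all(fits$summary$ci_low < fits$summary$ci_high))
})

test_that("Wald intervals for a single log-OR reach near-nominal coverage", {
  beta_true <- log(1.6)
  covered <- 0
  n_sim <- 200
  set.seed(77)
  for (s in seq_len(n_sim)) {
    n_pat <- 15; per <- 20
    pid <- rep(sprintf("p%02d", 1:n_pat), each = per)
    b <- rnorm(n_pat, 0, 0.8)[rep(1:n_pat, each = per)]
    x <- rbinom(n_pat * per, 1, 0.4)
    y <- rbinom(n_pat * per, 1, plogis(-1.2 + beta_true * x + b))
    if (length(unique(y)) < 2) next
    fit <- try(fit_mixed_logistic(
      data.frame(patient_id = pid, x = x, label = y),
      label ~ x, quad_points = 9), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$ci_low["x"] <= exp(beta_true) &&
        exp(beta_true) <= fit$ci_high["x"]) covered <- covered + 1
  }
  expect_gte(covered / n_sim, 0.89)
  expect_lte(covered / n_sim, 0.99)
})
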