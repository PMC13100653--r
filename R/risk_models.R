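#' Mixed-effects logistic regression with a patient random intercept
#'
#' Fits `label ~ features + (1 | patient_id)` by maximum likelihood,
#' integrating the per-patient random intercept with adaptive Gauss--Hermite
#' quadrature (`quad_points` nodes; 1 node is the Laplace approximation).
#' Between-patient heterogeneity in IDH propensity is large in monitored
#' dialysis cohorts, so the random intercept is essential: it absorbs
#' patient-level risk and leaves the fixed effects to describe the
#' within-session physiology.
#'
#' @param rows prediction rows from [build_rows()] (needs `label`,
#'   `patient_id` and the features in `formula`).
#' @param formula fixed-effects formula, e.g. `label ~ delta_rbv` (the
#'   random intercept is added automatically; a `(1 | patient_id)` term may
#'   also be written explicitly).
#' @param quad_points adaptive Gauss--Hermite nodes (default 21).
#' @return An object of class `mixed_logistic_fit`: `coef` (fixed effects),
#'   `se`, `or` (`exp(coef)`), `ci_low`/`ci_high` (95% Wald), `p_value`,
#'   `sigma_b`, `ranef` (per-patient posterior modes), `loglik`,
#'   `convergence`, `n_obs`, `n_patients`, plus the underlying `glmerMod`
#'   in `$model`.
#' @export
fit_mixed_logistic <- function(rows, formula, quad_points = 21) {
  if (length(unique(rows$patient_id)) < 2) {
    stop("need at least 2 patients to fit a random intercept")
  }
  y <- rows[[all.vars(formula)[1]]]
  if (length(unique(y)) < 2) stop("outcome is constant; nothing to fit")
  # crude separation screen on the fixed part
  fe_only <- lme4::nobars(formula)
  g0 <- suppressWarnings(glm(fe_only, data = rows, family = binomial()))
  pr <- predict(g0, type = "response")
  if (all(pr[y == 1] > 1 - 1e-8) && all(pr[y == 0] < 1e-8)) {
    stop("complete separation in the fixed effects; remove or penalize ",
         "the offending covariate")
  }
  f <- if (length(lme4::findbars(formula))) formula else {
    stats::update(formula, . ~ . + (1 | patient_id))
  }
  fit <- lme4::glmer(f, data = rows, family = binomial(),
                     nAGQ = quad_points,
                     control = lme4::glmerControl(calc.derivs = TRUE))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  conv <- fit@optinfo$conv
  z <- beta / se
  re <- lme4::ranef(fit)$patient_id
  structure(list(
    coef = beta, se = se,
    or = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
    sigma_b = sqrt(unname(unlist(lme4::VarCorr(fit)))),
    ranef = setNames(re[["(Intercept)"]], rownames(re)),
    loglik = as.numeric(logLik(fit)),
    convergence = list(opt = conv$opt,
                       messages = unlist(conv$lme4$messages)),
    n_obs = nrow(stats::model.frame(fit)),
    n_patients = nrow(re),
    formula = f,
    model = fit
  ), class = "mixed_logistic_fit")
}

#' @export
print.mixed_logistic_fit <- function(x, digits = 3, ...) {
  cat("Mixed-effects logistic fit:", deparse(x$formula), "\n")
  cat(sprintf("  %d obs, %d patients; sigma_b = %.3f; logLik = %.1f\n",
              x$n_obs, x$n_patients, x$sigma_b, x$loglik))
  tab <- data.frame(coef = x$coef, se = x$se, OR = x$or,
                    ci_low = x$ci_low, ci_high = x$ci_high, p = x$p_value)
  print(round(tab, digits))
  invisible(x)
}

#' Predict event probabilities from a mixed logistic fit
#'
#' Fixed-effects linear predictor plus, when `use_random_effects = TRUE`,
#' the posterior-mode intercept of each patient seen in training. Patients
#' absent from the training data always get fixed-effects-only predictions —
#' random effects cannot be estimated for unseen patients.
#'
#' @param object a `mixed_logistic_fit`.
#' @param rows prediction rows with the model's features (and `patient_id`).
#' @param use_random_effects add estimated patient intercepts where
#'   available? Default `FALSE`.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.mixed_logistic_fit <- function(object, rows,
                                       use_random_effects = FALSE, ...) {
  fe <- lme4::nobars(object$formula)
  terms <- stats::delete.response(stats::terms(fe))
  mf <- stats::model.frame(terms, rows)
  X <- stats::model.matrix(terms, mf)
  if (!all(colnames(X) %in% names(object$coef))) {
    stop("rows contain feature levels unseen in training")
  }
  eta <- drop(X %*% object$coef[colnames(X)])
  if (use_random_effects) {
    b <- object$ranef[as.character(rows$patient_id)]
    b[is.na(b)] <- 0
    eta <- eta + b
  }
  plogis(eta)
}

#' Concurrent association suite
#'
#' The three concurrent-mode association models, each with a patient random
#' intercept: IDH at the time of measurement against (1) the continuous RBV
#' decline `delta_rbv`, (2) high- vs low-risk trajectory cluster membership,
#' and (3) the below-dynamic-threshold indicator.
#'
#' @param rows concurrent-mode rows from [build_rows()]; must already carry
#'   `below_threshold` if the threshold model is wanted.
#' @param risk_groups optional [assign_risk_groups()] result (or named
#'   vector); enables the cluster model by attaching the session-level
#'   covariate.
#' @param quad_points passed to [fit_mixed_logistic()].
#' @return named list of `mixed_logistic_fit`s (`delta_rbv`, `risk_group`,
#'   `below_threshold`; entries absent when their covariate is unavailable)
#'   with a `summary` data frame of OR, 95% Wald CI and p per model.
#' @export
fit_association_suite <- function(rows, risk_groups = NULL,
                                  quad_points = 21) {
  fits <- list()
  fits$delta_rbv <- fit_mixed_logistic(rows, label ~ delta_rbv, quad_points)
  if (!is.null(risk_groups)) {
    rg <- if (inherits(risk_groups, "risk_groups")) risk_groups$risk_group
          else risk_groups
    rows$risk_group_high <-
      as.integer(rg[as.character(rows$session_id)] == "high")
    fits$risk_group <- fit_mixed_logistic(rows, label ~ risk_group_high,
                                          quad_points)
  }
  if ("below_threshold" %in% names(rows)) {
    fits$below_threshold <- fit_mixed_logistic(rows, label ~ below_threshold,
                                               quad_points)
  }
  fits$summary <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, term = names(f$coef)[2],
               or = unname(f$or[2]), ci_low = unname(f$ci_low[2]),
               ci_high = unname(f$ci_high[2]), p = unname(f$p_value[2]),
               sigma_b = f$sigma_b)
  }))
  fits
}

#' Predictive (10--60 minute horizon) model
#'
#' Fits the near-future risk model on horizon-mode rows: IDH occurring in
#' the 10--60 minutes after a measurement, as a function of the
#' measurement's features. The default formula is the five-covariate
#' multivariable model (below-threshold indicator + dRBV/dt + SBP + ΔSBP +
#' HR); pass e.g. `label ~ delta_rbv` for the RBV-only predictive model.
#'
#' @param rows horizon-mode rows from [build_rows()].
#' @param formula fixed-effects formula; random intercept added
#'   automatically.
#' @param quad_points passed to [fit_mixed_logistic()].
#' @return A `mixed_logistic_fit`.
#' @export
fit_predictive_model <- function(rows,
                                 formula = label ~ below_threshold +
                                   drbv_dt + sbp + delta_sbp + hr,
                                 quad_points = 21) {
  fit_mixed_logistic(rows, formula, quad_points)
}
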