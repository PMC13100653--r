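#' Train/test split of dialysis sessions
#'
#' Two validation designs:
#' \describe{
#'   \item{patient}{random partition of patients; all of a patient's
#'     sessions land on one side. Emulates deployment on entirely unseen
#'     patients, for whom random effects cannot be used.}
#'   \item{session}{chronological within patient: each patient's earliest
#'     `ceiling(fraction * n_i)` sessions train, the remainder test.
#'     Emulates applying a model to future sessions of known patients. A
#'     patient with a single session contributes it to training.}
#' }
#'
#' @param sessions the cohort `sessions` table (`patient_id`, `session_id`,
#'   `session_order`).
#' @param mode `"patient"` or `"session"`.
#' @param fraction training fraction in (0, 1).
#' @param seed seed (patient mode's random partition).
#' @return list with `train` and `test` session-id character vectors.
#' @export
split_sessions <- function(sessions, mode = c("session", "patient"),
                           fraction = 0.7, seed = 1) {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be strictly between 0 and 1")
  }
  if (mode == "patient") {
    set.seed(seed)
    pats <- unique(sessions$patient_id)
    n_tr <- max(1, round(fraction * length(pats)))
    if (n_tr >= length(pats)) n_tr <- length(pats) - 1
    if (n_tr < 1) stop("too few patients to split")
    tr_pats <- sample(pats, n_tr)
    train <- sessions$session_id[sessions$patient_id %in% tr_pats]
    test <- sessions$session_id[!sessions$patient_id %in% tr_pats]
  } else {
    parts <- lapply(split(sessions, sessions$patient_id), function(s) {
      s <- s[order(s$session_order), , drop = FALSE]
      n_tr <- ceiling(fraction * nrow(s))
      list(train = s$session_id[seq_len(n_tr)],
           test = if (n_tr < nrow(s)) s$session_id[(n_tr + 1):nrow(s)]
                  else character(0))
    })
    train <- unlist(lapply(parts, `[[`, "train"), use.names = FALSE)
    test <- unlist(lapply(parts, `[[`, "test"), use.names = FALSE)
  }
  if (length(test) == 0) stop("empty test side; lower the fraction")
  list(train = as.character(train), test = as.character(test))
}

#' ROC area under the curve
#'
#' Concordance probability: the chance a random positive scores above a
#' random negative, ties counted one half — equivalent to trapezoidal
#' integration of the ROC curve, computed via the rank formula.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcomes.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden operating point
#'
#' Scans the unique scores as candidate thresholds (predict positive when
#' `score >= threshold`) and returns the one maximizing the Youden index,
#' with the full metric set of its 2x2 table.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcomes (both classes present).
#' @return list: `threshold`, `sensitivity`, `specificity`, `npv`, `ppv`,
#'   `youden`, and `confusion` (`tp`, `fp`, `tn`, `fn`).
#' @export
operating_point <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("need both classes present")
  cand <- sort(unique(scores))
  best <- NULL
  for (thr in cand) {
    pred <- as.integer(scores >= thr)
    tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
    tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    J <- sens + spec - 1
    if (is.null(best) || J > best$youden + 1e-12) {
      best <- list(threshold = thr, sensitivity = sens, specificity = spec,
                   npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                   ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                   youden = J,
                   confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
    }
  }
  best
}

#' Fit, predict and score a risk model under a validation split
#'
#' Splits sessions, fits the mixed logistic model on the training rows,
#' predicts the test rows (random effects only under the session-wise
#' design, where test patients were seen in training) and reports
#' discrimination and the Youden operating point.
#'
#' @param rows prediction rows from [build_rows()].
#' @param sessions the cohort `sessions` table.
#' @param formula fixed-effects formula for [fit_mixed_logistic()].
#' @param mode split mode, `"session"` or `"patient"`.
#' @param fraction training fraction.
#' @param seed split seed.
#' @param use_random_effects `NULL` (default) uses random effects iff
#'   `mode == "session"`; or force with `TRUE`/`FALSE`.
#' @param quad_points passed to the fitter.
#' @return list of class `evaluation_report`: the split spec, `fit`,
#'   `auc_train`, `auc_test`, operating-point metrics on the test side, and
#'   side sizes.
#' @export
evaluate_model <- function(rows, sessions, formula = label ~ delta_rbv,
                           mode = c("session", "patient"), fraction = 0.7,
                           seed = 1, use_random_effects = NULL,
                           quad_points = 21) {
  mode <- match.arg(mode)
  if (is.null(use_random_effects)) use_random_effects <- mode == "session"
  sp <- split_sessions(sessions, mode = mode, fraction = fraction,
                       seed = seed)
  tr <- rows[rows$session_id %in% sp$train, , drop = FALSE]
  te <- rows[rows$session_id %in% sp$test, , drop = FALSE]
  fit <- fit_mixed_logistic(tr, formula, quad_points)
  p_tr <- predict(fit, tr, use_random_effects = use_random_effects)
  p_te <- predict(fit, te, use_random_effects = use_random_effects)
  op <- if (length(unique(te$label)) == 2) operating_point(p_te, te$label)
  structure(list(
    split = list(mode = mode, fraction = fraction, seed = seed,
                 use_random_effects = use_random_effects),
    fit = fit,
    auc_train = roc_auc(p_tr, tr$label),
    auc_test = roc_auc(p_te, te$label),
    operating = op,
    n = list(train_rows = nrow(tr), test_rows = nrow(te),
             train_sessions = length(sp$train),
             test_sessions = length(sp$test))
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%s-wise split (fraction %.2f): train AUC %.3f, test AUC %.3f\n",
              x$split$mode, x$split$fraction, x$auc_train, x$auc_test))
  if (!is.null(x$operating)) {
    cat(sprintf("  test operating point: sens %.2f, spec %.2f, npv %.2f\n",
                x$operating$sensitivity, x$operating$specificity,
                x$operating$npv))
  }
  invisible(x)
}

#' Descriptive association analyses
#'
#' The descriptive counterparts of the model fits:
#' \describe{
#'   \item{rbv_bins}{IDH frequency within RBV categories (>= 95, 90--95,
#'     85--90, 80--85, < 80; left-closed lower edges), each compared with
#'     the >= 95% reference bin by Fisher's exact test.}
#'   \item{wilcoxon}{rank-sum comparison of concurrent RBV between
#'     hypotensive and non-hypotensive vitals entries (normal approximation
#'     with tie correction).}
#'   \item{interval_fisher}{per 30-minute interval, Fisher's exact test of
#'     cumulative session-level IDH (any event by the interval's end)
#'     between high- and low-risk groups.}
#' }
#'
#' @param rows concurrent-mode rows from [build_rows()].
#' @param risk_groups optional [assign_risk_groups()] result for the
#'   interval analysis.
#' @param interval_min interval width for the cumulative comparison.
#' @return list with `rbv_bins`, `wilcoxon`, and (given risk groups)
#'   `interval_fisher` data frames.
#' @export
descriptive_suite <- function(rows, risk_groups = NULL, interval_min = 30) {
  edges <- c(-Inf, 80, 85, 90, 95, Inf)
  lab <- c("<80", "80-85", "85-90", "90-95", ">=95")
  bin <- cut(rows$rbv_pct, breaks = edges, labels = lab, right = FALSE)
  ref <- rows$label[bin == ">=95"]
  bins <- do.call(rbind, lapply(lab, function(bl) {
    y <- rows$label[bin == bl]
    if (length(y) == 0) return(NULL)
    p <- if (bl == ">=95" || length(ref) == 0) NA_real_ else {
      tab <- matrix(c(sum(y == 1), sum(y == 0),
                      sum(ref == 1), sum(ref == 0)), nrow = 2)
      fisher.test(tab)$p.value
    }
    data.frame(bin = bl, n = length(y), events = sum(y == 1),
               idh_freq = mean(y == 1), p_vs_ref = p)
  }))
  wt <- if (length(unique(rows$label)) == 2) {
    w <- suppressWarnings(
      wilcox.test(rbv_pct ~ label, data = rows, exact = FALSE,
                  correct = TRUE))
    # fully tied samples: no evidence either way
    pw <- if (is.nan(w$p.value)) 1 else w$p.value
    data.frame(median_idh = median(rows$rbv_pct[rows$label == 1]),
               median_no_idh = median(rows$rbv_pct[rows$label == 0]),
               p = pw)
  }
  out <- list(rbv_bins = bins, wilcoxon = wt)
  if (!is.null(risk_groups)) {
    rg <- if (inherits(risk_groups, "risk_groups")) risk_groups$risk_group
          else risk_groups
    ses_first <- tapply(
      ifelse(rows$label == 1, rows$t_min, Inf),
      as.character(rows$session_id), min)
    grp <- rg[names(ses_first)]
    marks <- seq(interval_min, max(rows$t_min), by = interval_min)
    out$interval_fisher <- do.call(rbind, lapply(marks, function(tm) {
      ev <- ses_first <= tm
      tab <- table(factor(grp, c("high", "low")), factor(ev, c(TRUE, FALSE)))
      data.frame(t_min = tm,
                 cum_idh_high = mean(ev[grp == "high"]),
                 cum_idh_low = mean(ev[grp == "low"]),
                 p = fisher.test(tab)$p.value)
    }))
  }
  out
}
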