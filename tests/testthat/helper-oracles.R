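# Independent brute-force oracles and small fixtures shared across tests.

# DTW by exhaustive enumeration of all monotone warping paths (tiny series).
dtw_brute <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, 0)
  best
}

# Exhaustive k-medoids cost over all medoid subsets.
kmedoids_brute_cost <- function(d, k) {
  combs <- utils::combn(nrow(d), k)
  min(apply(combs, 2, function(med) {
    sum(apply(d[, med, drop = FALSE], 1, min))
  }))
}

# AUC by direct counting over positive-negative pairs (ties = 1/2).
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher exact p by hypergeometric enumeration on a 2x2 table
# (rows: groups, cols: event / no event).
fisher_brute <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); kk <- sum(tab[, 1])
  ks <- max(0, kk - n2):min(kk, m)
  probs <- stats::dhyper(ks, m, n2, kk)
  p_obs <- stats::dhyper(tab[1, 1], m, n2, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Best Youden J over the midpoint candidate cutoffs (value only).
youden_brute <- function(hi, lo) {
  pooled <- sort(unique(c(hi, lo)))
  cand <- (head(pooled, -1) + pooled[-1]) / 2
  max(vapply(cand, function(c) mean(hi < c) + mean(lo >= c) - 1, 0))
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  sij <- sum(choose(ct, 2))
  si <- sum(choose(rowSums(ct), 2))
  sj <- sum(choose(colSums(ct), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Gauss-Hermite log-likelihood of a random-intercept logistic model at given
# parameters; independent of lme4 (plain quadrature, 61 nodes via
# eigen-decomposition of the Jacobi matrix).
gh_nodes <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

glmm_loglik_brute <- function(beta, sigma_b, X, y, patient, n_nodes = 61) {
  gh <- gh_nodes(n_nodes)
  eta0 <- drop(X %*% beta)
  ll <- 0
  for (pid in unique(patient)) {
    idx <- patient == pid
    contrib <- vapply(seq_along(gh$x), function(q) {
      b <- sqrt(2) * sigma_b * gh$x[q]
      p <- plogis(eta0[idx] + b)
      exp(sum(stats::dbinom(y[idx], 1, p, log = TRUE)))
    }, numeric(1))
    ll <- ll + log(sum(gh$w * contrib) / sqrt(pi))
  }
  ll
}

# Small fast cohort configuration for unit tests.
tiny_config <- function(...) {
  cohort_config(n_patients = 12, sessions_per_patient = 4,
                duration_min = 120, vitals_interval_min = 30, ...)
}

tiny_continuous_effect <- function(intercept = -2.5, sigma_b = 1,
                                   or = 1.08) {
  effect_spec("continuous", intercept = intercept,
              terms = c(delta_rbv = log(or)), sigma_b = sigma_b)
}

# Hand-built two-group cohort of constant-level RBV trajectories (for
# threshold tests): n_hi sessions at level_hi, n_lo at level_lo.
constant_cohort <- function(level_hi, level_lo, n_hi = 3, n_lo = 3,
                            duration = 60, ht0 = 33) {
  mk <- function(id, lev, pid, ord) {
    rbv <- c(100, rep(lev, duration))
    list(
      sessions = data.frame(patient_id = pid, session_id = id,
                            session_order = ord, duration_min = duration),
      machine = data.frame(session_id = id, t_min = 0:duration,
                           hematocrit_pct = ht0 * 100 / rbv, rbv_pct = rbv),
      vitals = data.frame(session_id = id, t_min = c(0, 30, 60),
                          sbp = c(130, 120, 110), dbp = c(70, 68, 66),
                          hr = c(70, 72, 74))
    )
  }
  parts <- c(
    lapply(seq_len(n_hi), function(i)
      mk(sprintf("H%02d", i), level_hi, sprintf("pH%02d", i), 1)),
    lapply(seq_len(n_lo), function(i)
      mk(sprintf("L%02d", i), level_lo, sprintf("pL%02d", i), 1))
  )
  co <- rbv_cohort(do.call(rbind, lapply(parts, `[[`, "sessions")),
                   do.call(rbind, lapply(parts, `[[`, "machine")),
                   do.call(rbind, lapply(parts, `[[`, "vitals")),
                   validate = FALSE)
  rg <- setNames(rep(c("high", "low"), c(n_hi, n_lo)),
                 c(sprintf("H%02d", seq_len(n_hi)),
                   sprintf("L%02d", seq_len(n_lo))))
  list(cohort = co, risk_groups = rg)
}
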