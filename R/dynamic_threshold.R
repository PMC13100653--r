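#' Time-dependent RBV threshold curve
#'
#' Container for the dynamic RBV threshold: at each grid time, the RBV
#' cutoff that best separates high- from low-risk trajectory groups
#' (Youden-index maximization), together with its LOESS smoothing and
#' pointwise bootstrap band.
#'
#' @param t_min grid times (minutes).
#' @param raw raw per-timepoint Youden cutoffs (%).
#' @param smooth LOESS-smoothed cutoffs (%).
#' @param ci_low,ci_high pointwise bootstrap band (%); clipped so that
#'   `ci_low <= smooth <= ci_high` holds everywhere.
#' @param params list of derivation parameters (span, B, seed, ...).
#' @return An object of class `threshold_curve` (a data frame with columns
#'   `t_min`, `raw`, `smooth`, `ci_low`, `ci_high`).
#' @export
threshold_curve <- function(t_min, raw, smooth = raw, ci_low = smooth,
                            ci_high = smooth, params = list()) {
  ci_low <- pmin(ci_low, smooth)
  ci_high <- pmax(ci_high, smooth)
  structure(data.frame(t_min = t_min, raw = raw, smooth = smooth,
                       ci_low = ci_low, ci_high = ci_high),
            params = params,
            class = c("threshold_curve", "data.frame"))
}

#' Youden-optimal RBV cutoff at one timepoint
#'
#' Enumerates candidate cutoffs at the midpoints between adjacent distinct
#' pooled RBV values, classifying "RBV below cutoff" as high risk, and
#' returns the cutoff maximizing the Youden index
#' J = sensitivity + specificity - 1 (sensitivity: fraction of high-risk
#' values below the cutoff; specificity: fraction of low-risk values at or
#' above it). When several contiguous candidates tie at the maximum, the
#' midpoint of the first maximizing interval (bounded by the adjacent data
#' values) is returned — for perfectly separated groups this is the centre
#' of the separating gap.
#'
#' @param values_high RBV values (%) from high-risk sessions at this time.
#' @param values_low RBV values (%) from low-risk sessions at this time.
#' @return list with `cutoff` and `J`.
#' @export
youden_threshold_at_time <- function(values_high, values_low) {
  if (length(values_high) == 0 || length(values_low) == 0) {
    stop("both risk groups must be non-empty at this timepoint")
  }
  pooled <- sort(unique(c(values_high, values_low)))
  if (length(pooled) == 1) {
    return(list(cutoff = pooled, J = 0))
  }
  cand <- (head(pooled, -1) + pooled[-1]) / 2
  J <- vapply(cand, function(c) {
    mean(values_high < c) + mean(values_low >= c) - 1
  }, numeric(1))
  jmax <- max(J)
  is_max <- abs(J - jmax) < 1e-12
  # first contiguous run of maximizing candidates; its spanning interval is
  # (pooled[i], pooled[j + 1]) for candidate indices i..j
  first <- which(is_max)[1]
  last <- first
  while (last < length(cand) && is_max[last + 1]) last <- last + 1
  cutoff <- (pooled[first] + pooled[last + 1]) / 2
  list(cutoff = cutoff, J = jmax)
}

#' Raw time-dependent threshold
#'
#' At each grid time t, pools the RBV values at minute t of all sessions
#' still running (duration >= t) in each risk group and applies
#' [youden_threshold_at_time()]. Grid points where either group has no
#' running session are skipped.
#'
#' @param cohort an `rbv_cohort`.
#' @param risk_groups a [assign_risk_groups()] result, or a named
#'   `"high"`/`"low"` character vector per session.
#' @param grid_step_min grid step (default 5 minutes).
#' @return data frame with `t_min`, `raw` (cutoff) and `J`.
#' @export
derive_raw_threshold <- function(cohort, risk_groups, grid_step_min = 5) {
  rg <- if (inherits(risk_groups, "risk_groups")) risk_groups$risk_group
        else risk_groups
  if (!all(c("high", "low") %in% rg)) {
    stop("need at least one session in each risk group")
  }
  rbv_split <- split(cohort$machine$rbv_pct, cohort$machine$session_id)
  dur <- setNames(cohort$sessions$duration_min,
                  as.character(cohort$sessions$session_id))
  ids <- names(rbv_split)
  grid <- seq(0, max(dur), by = grid_step_min)
  rows <- lapply(grid, function(t) {
    running <- ids[dur[ids] >= t]
    vals <- vapply(running, function(s) rbv_split[[s]][t + 1L], numeric(1))
    hi <- vals[rg[running] == "high"]
    lo <- vals[rg[running] == "low"]
    if (length(hi) == 0 || length(lo) == 0) return(NULL)
    yt <- youden_threshold_at_time(hi, lo)
    data.frame(t_min = t, raw = yt$cutoff, J = yt$J)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' LOESS smoothing of the raw threshold
#'
#' Local linear regression with tricube weights over the span-fraction
#' nearest neighbours (`stats::loess`, degree 1), evaluated at each input
#' x.
#'
#' @param x,y numeric vectors (at least 4 points; `x` not all equal).
#' @param span fraction of points in each local neighbourhood, in (0, 1].
#' @return fitted values at `x`.
#' @export
loess_smooth <- function(x, y, span = 0.3) {
  if (length(x) < 4) stop("need at least 4 points to smooth")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (diff(range(x)) == 0) stop("degenerate x: all values equal")
  fit <- loess(y ~ x, span = span, degree = 1,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  as.numeric(predict(fit, newdata = data.frame(x = x)))
}

#' Bootstrap band for the smoothed threshold
#'
#' Resamples sessions with replacement within each risk group, re-derives
#' the raw threshold and its LOESS smoothing per replicate, and takes
#' pointwise percentile intervals on the base grid. Replicates where a grid
#' point loses both-group support contribute `NA` there.
#'
#' @param cohort an `rbv_cohort`.
#' @param risk_groups as in [derive_raw_threshold()].
#' @param B number of bootstrap replicates (>= 100 recommended for reported
#'   runs).
#' @param span LOESS span.
#' @param level interval level (default 0.95).
#' @param grid_step_min grid step.
#' @param seed seed for the resampling.
#' @return list with `t_min`, `ci_low`, `ci_high`.
#' @export
bootstrap_threshold_ci <- function(cohort, risk_groups, B = 200,
                                   span = 0.3, level = 0.95,
                                   grid_step_min = 5, seed = 1) {
  rg <- if (inherits(risk_groups, "risk_groups")) risk_groups$risk_group
        else risk_groups
  set.seed(seed)
  base <- derive_raw_threshold(cohort, rg, grid_step_min)
  ids_hi <- names(rg)[rg == "high"]
  ids_lo <- names(rg)[rg == "low"]
  ses <- cohort$sessions
  mach_split <- split(cohort$machine, cohort$machine$session_id)
  reps <- matrix(NA_real_, nrow = B, ncol = nrow(base))
  for (b in seq_len(B)) {
    draw <- c(sample(ids_hi, length(ids_hi), replace = TRUE),
              sample(ids_lo, length(ids_lo), replace = TRUE))
    # rebuild a cohort of the resampled sessions under fresh unique ids
    new_id <- sprintf("B%05d", seq_along(draw))
    m <- do.call(rbind, lapply(seq_along(draw), function(i) {
      mi <- mach_split[[draw[i]]]
      mi$session_id <- new_id[i]
      mi
    }))
    s <- ses[match(draw, ses$session_id), , drop = FALSE]
    s$session_id <- new_id
    rg_b <- setNames(rep(c("high", "low"),
                         c(length(ids_hi), length(ids_lo))), new_id)
    boot_cohort <- structure(list(sessions = s, machine = m),
                             class = "rbv_cohort")
    raw_b <- tryCatch(derive_raw_threshold(boot_cohort, rg_b, grid_step_min),
                      error = function(e) NULL)
    if (is.null(raw_b) || nrow(raw_b) < 4) next
    # degenerate replicates (e.g. constant raw values) provoke harmless
    # loess conditioning warnings
    sm <- suppressWarnings(loess_smooth(raw_b$t_min, raw_b$raw, span))
    reps[b, ] <- approx(raw_b$t_min, sm, xout = base$t_min, rule = 1)$y
  }
  a <- (1 - level) / 2
  list(t_min = base$t_min,
       ci_low = apply(reps, 2, quantile, probs = a, na.rm = TRUE,
                      names = FALSE),
       ci_high = apply(reps, 2, quantile, probs = 1 - a, na.rm = TRUE,
                       names = FALSE))
}

#' Derive the full threshold curve
#'
#' Convenience wrapper: raw Youden threshold on the grid, LOESS smoothing,
#' and (optionally) the bootstrap band, assembled into a
#' [threshold_curve()].
#'
#' @inheritParams bootstrap_threshold_ci
#' @param B bootstrap replicates; `0` skips the band (it then equals the
#'   smooth curve).
#' @return A [threshold_curve].
#' @export
derive_threshold_curve <- function(cohort, risk_groups, grid_step_min = 5,
                                   span = 0.3, B = 0, level = 0.95,
                                   seed = 1) {
  raw <- derive_raw_threshold(cohort, risk_groups, grid_step_min)
  sm <- loess_smooth(raw$t_min, raw$raw, span)
  if (B > 0) {
    ci <- bootstrap_threshold_ci(cohort, risk_groups, B = B, span = span,
                                 level = level,
                                 grid_step_min = grid_step_min, seed = seed)
    lo <- approx(ci$t_min, ci$ci_low, xout = raw$t_min, rule = 2)$y
    hi <- approx(ci$t_min, ci$ci_high, xout = raw$t_min, rule = 2)$y
  } else {
    lo <- hi <- sm
  }
  threshold_curve(raw$t_min, raw$raw, sm, lo, hi,
                  params = list(span = span, B = B, level = level,
                                seed = seed, grid_step_min = grid_step_min))
}

#' Below-threshold indicator
#'
#' Is the RBV value strictly below the smoothed threshold at time t? The
#' threshold is linearly interpolated between grid points; outside the
#' curve's support the nearest grid point's value is used. Equality is not
#' a crossing (strict inequality).
#'
#' @param rbv_pct RBV value(s) (%).
#' @param curve a [threshold_curve].
#' @param t_min time(s) (minutes) of the values.
#' @return integer 0/1 vector.
#' @export
below_threshold <- function(rbv_pct, curve, t_min) {
  thr <- approx(curve$t_min, curve$smooth, xout = t_min, rule = 2)$y
  as.integer(rbv_pct < thr)
}
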