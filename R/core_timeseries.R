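#' Compute relative blood volume from a hematocrit series
#'
#' RBV(t) is the percentage of baseline intravascular blood volume remaining
#' at time t, estimated from continuous hematocrit monitoring as
#' `100 * Ht(0) / Ht(t)`: as ultrafiltration removes plasma water faster than
#' vascular refilling replaces it, hematocrit rises and RBV falls.
#'
#' @param hematocrit_pct numeric vector of per-minute hematocrit readings
#'   (percent, strictly inside (0, 100)), starting at session minute 0.
#' @param baseline how `Ht(0)` is taken: `"first"` (default) uses the first
#'   reading, so `rbv[1] == 100` exactly; `"mean"` uses the mean over minutes
#'   0--2, a noise-robust choice for real sensor data (then `rbv[1]` may
#'   deviate slightly from 100).
#' @return numeric vector of RBV values (percent), same length as the input.
#' @examples
#' compute_rbv(c(30, 30, 37.5))  # 100, 100, 80
#' @export
compute_rbv <- function(hematocrit_pct, baseline = c("first", "mean")) {
  baseline <- match.arg(baseline)
  if (length(hematocrit_pct) == 0) stop("hematocrit series is empty")
  bad <- which(!is.finite(hematocrit_pct) |
                 hematocrit_pct <= 0 | hematocrit_pct >= 100)
  if (length(bad)) {
    stop("hematocrit out of (0, 100) at index ", bad[1],
         " (value ", hematocrit_pct[bad[1]], ")")
  }
  ht0 <- switch(baseline,
    first = hematocrit_pct[1],
    mean = mean(hematocrit_pct[seq_len(min(3, length(hematocrit_pct)))])
  )
  100 * ht0 / hematocrit_pct
}

#' Label intradialytic hypotension events
#'
#' An intermittent vitals entry is flagged as IDH when systolic blood
#' pressure is below 90 mmHg *and* has dropped by at least 20 mmHg from the
#' session baseline (the first recorded SBP of the session). The absolute
#' nadir criterion follows the outcome-validated definition (nadir SBP
#' < 90 mmHg); the drop criterion anchors it to the pre-dialysis pressure,
#' which dialysis interventions cannot have influenced.
#'
#' @param vitals data frame with columns `t_min` and `sbp`, ordered by time.
#' @param baseline_sbp session baseline SBP; defaults to the first recorded
#'   SBP (smallest `t_min`).
#' @return A list of class `idh_labels`: `idh` (logical per entry),
#'   `any_idh`, `first_event_time_min` (`NA` if event-free), `baseline_sbp`.
#' @export
label_idh <- function(vitals, baseline_sbp = NULL) {
  if (is.null(vitals) || nrow(vitals) == 0) stop("vitals table is empty")
  ord <- order(vitals$t_min)
  vitals <- vitals[ord, , drop = FALSE]
  if (is.null(baseline_sbp)) baseline_sbp <- vitals$sbp[1]
  flag <- vitals$sbp < 90 & (baseline_sbp - vitals$sbp) >= 20
  structure(
    list(
      idh = flag,
      t_min = vitals$t_min,
      any_idh = any(flag),
      first_event_time_min = if (any(flag)) min(vitals$t_min[flag]) else NA_real_,
      baseline_sbp = baseline_sbp
    ),
    class = "idh_labels"
  )
}

#' Label IDH across a whole cohort
#'
#' Applies [label_idh()] session by session.
#'
#' @param cohort an `rbv_cohort`.
#' @return A list with `vitals` (the cohort vitals table plus an `idh`
#'   column) and `sessions` (`session_id`, `any_idh`,
#'   `first_event_time_min`, `baseline_sbp`).
#' @export
label_idh_cohort <- function(cohort) {
  vit <- cohort$vitals
  vit <- vit[order(vit$session_id, vit$t_min), , drop = FALSE]
  per <- lapply(split(vit, vit$session_id), function(v) {
    lab <- label_idh(v)
    v$idh <- lab$idh
    list(vitals = v,
         summary = data.frame(
           session_id = v$session_id[1],
           any_idh = lab$any_idh,
           first_event_time_min = lab$first_event_time_min,
           baseline_sbp = lab$baseline_sbp
         ))
  })
  out_v <- do.call(rbind, lapply(per, `[[`, "vitals"))
  out_s <- do.call(rbind, lapply(per, `[[`, "summary"))
  rownames(out_v) <- rownames(out_s) <- NULL
  list(vitals = out_v, sessions = out_s)
}

#' Trailing slope of the RBV series
#'
#' Ordinary-least-squares slope of RBV over the trailing window
#' `[t - window_min, t]` on the minute grid, in percent per minute; negative
#' while RBV is falling. Near the session start the window is truncated at
#' t = 0; with fewer than two in-window points the slope is undefined (`NA`).
#'
#' @param rbv_series per-minute RBV values for grid minutes `0..(length-1)`.
#' @param t minute (or vector of minutes) at which to evaluate the slope.
#' @param window_min trailing window length in minutes (default 10).
#' @return numeric slope(s), `NA` where undefined.
#' @export
compute_drbv_dt <- function(rbv_series, t, window_min = 10) {
  n <- length(rbv_series)
  vapply(t, function(ti) {
    if (ti < 0 || ti > n - 1) return(NA_real_)
    lo <- max(0, ti - window_min)
    idx <- (lo:ti) + 1L
    if (length(idx) < 2) return(NA_real_)
    x <- (lo:ti)
    y <- rbv_series[idx]
    xc <- x - mean(x)
    sum(xc * (y - mean(y))) / sum(xc^2)
  }, numeric(1))
}

#' Assemble per-measurement prediction rows
#'
#' One row per eligible intermittent vitals entry, carrying the features the
#' risk models use: `rbv_pct` (RBV at the measurement minute), `delta_rbv`
#' (= 100 - RBV), `drbv_dt` (trailing OLS slope, %/min), `sbp`, `delta_sbp`
#' (= session baseline SBP - current SBP), `hr`, and optionally
#' `below_threshold` (crossing indicator against a [threshold_curve]).
#'
#' Labels depend on `mode`:
#' \describe{
#'   \item{`"concurrent"`}{the entry's own IDH flag — association models of
#'     risk at the time of measurement.}
#'   \item{`"horizon"`}{1 iff any flagged vitals entry falls in
#'     `(t + horizon[1], t + horizon[2]]` (default `(t+10, t+60]`); the entry
#'     at t itself never contributes. Windows running past the session end
#'     are truncated there (counted in the `n_truncated` attribute). Rows
#'     where IDH is already ongoing at t are excluded by default, since
#'     predicting an event that has begun is clinically vacuous.}
#' }
#'
#' Rows whose `drbv_dt` is undefined (fewer than two in-window RBV points,
#' i.e. the t = 0 baseline entry) are dropped; the count is kept in the
#' `n_dropped_undefined` attribute.
#'
#' @param cohort an `rbv_cohort`.
#' @param labels output of [label_idh_cohort()]; computed if `NULL`.
#' @param mode `"concurrent"` or `"horizon"`.
#' @param horizon two-element numeric, the half-open look-ahead window
#'   `(t + horizon[1], t + horizon[2]]` in minutes.
#' @param threshold_curve optional [threshold_curve]; adds `below_threshold`.
#' @param drbv_window trailing window for `drbv_dt`, minutes.
#' @param exclude_ongoing horizon mode only: drop rows flagged at t itself?
#'   Default `TRUE`.
#' @return data frame of prediction rows with attributes `n_truncated` and
#'   `n_dropped_undefined`.
#' @export
build_rows <- function(cohort, labels = NULL,
                       mode = c("concurrent", "horizon"),
                       horizon = c(10, 60),
                       threshold_curve = NULL,
                       drbv_window = 10,
                       exclude_ongoing = TRUE) {
  mode <- match.arg(mode)
  if (is.null(labels)) labels <- label_idh_cohort(cohort)
  vit <- labels$vitals
  mach <- cohort$machine
  ses <- cohort$sessions
  pid_of <- setNames(ses$patient_id, as.character(ses$session_id))
  dur_of <- setNames(ses$duration_min, as.character(ses$session_id))
  rbv_split <- split(mach$rbv_pct, mach$session_id)

  n_trunc <- 0L
  n_drop <- 0L
  out <- lapply(split(vit, vit$session_id), function(v) {
    sid <- as.character(v$session_id[1])
    rbv <- rbv_split[[sid]]
    dur <- dur_of[[sid]]
    baseline_sbp <- v$sbp[which.min(v$t_min)]
    t <- v$t_min
    rbv_t <- rbv[t + 1L]
    slope <- compute_drbv_dt(rbv, t, window_min = drbv_window)
    rows <- data.frame(
      patient_id = pid_of[[sid]],
      session_id = v$session_id,
      t_min = t,
      rbv_pct = rbv_t,
      delta_rbv = 100 - rbv_t,
      drbv_dt = slope,
      sbp = v$sbp,
      delta_sbp = baseline_sbp - v$sbp,
      hr = v$hr,
      stringsAsFactors = FALSE
    )
    if (!is.null(threshold_curve)) {
      rows$below_threshold <- below_threshold(rbv_t, threshold_curve, t)
    }
    ev_times <- v$t_min[v$idh]
    if (mode == "concurrent") {
      rows$label <- as.integer(v$idh)
    } else {
      win_hi <- pmin(t + horizon[2], dur)
      n_trunc <<- n_trunc + sum(t + horizon[2] > dur)
      rows$label <- vapply(seq_along(t), function(i) {
        as.integer(any(ev_times > t[i] + horizon[1] & ev_times <= win_hi[i]))
      }, integer(1))
      if (exclude_ongoing) rows <- rows[!v$idh, , drop = FALSE]
    }
    rows
  })
  rows <- do.call(rbind, out)
  rownames(rows) <- NULL
  undef <- !is.finite(rows$drbv_dt)
  n_drop <- sum(undef)
  rows <- rows[!undef, , drop = FALSE]
  rows$label_mode <- mode
  attr(rows, "n_truncated") <- n_trunc
  attr(rows, "n_dropped_undefined") <- n_drop
  rows
}
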