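#' Cohort container
#'
#' An `rbv_cohort` bundles the three tables the pipeline operates on:
#' \describe{
#'   \item{sessions}{one row per dialysis session: `patient_id`, `session_id`,
#'     `session_order` (chronological rank within patient), `duration_min`.}
#'   \item{machine}{per-minute machine channel: `session_id`, `t_min`
#'     (integer minutes from session start, 0-based), `hematocrit_pct`,
#'     `rbv_pct` (derived, 100 at t = 0).}
#'   \item{vitals}{intermittent readings: `session_id`, `t_min`, `sbp`
#'     (systolic BP, mmHg), `dbp`, `hr` (bpm).}
#' }
#' A simulated cohort additionally carries a `truth` table (per-session
#' archetype, per-patient random intercept, simulated labels) used by
#' parameter-recovery tests.
#'
#' @param sessions,machine,vitals data frames as described above.
#' @param truth optional ground-truth data frame (simulated cohorts).
#' @param validate check invariants (minute grid, hematocrit range, baseline
#'   vitals)? Default `TRUE`.
#' @return An object of class `rbv_cohort`.
#' @export
rbv_cohort <- function(sessions, machine, vitals, truth = NULL, validate = TRUE) {
  sessions <- as.data.frame(sessions)
  machine <- as.data.frame(machine)
  vitals <- as.data.frame(vitals)
  obj <- structure(
    list(sessions = sessions, machine = machine, vitals = vitals, truth = truth),
    class = "rbv_cohort"
  )
  if (validate) validate_cohort(obj)
  obj
}

#' Validate cohort invariants
#'
#' Checks, per session: the minute grid is 0, 1, ..., duration; hematocrit is
#' strictly inside (0, 100); RBV at t = 0 equals 100 (when present); vitals
#' times lie on the minute grid with at least one entry at or before t = 5
#' (the session baseline reading).
#'
#' @param cohort an `rbv_cohort`.
#' @return `cohort`, invisibly; errors name the offending session.
#' @export
validate_cohort <- function(cohort) {
  s <- cohort$sessions
  need <- c("patient_id", "session_id", "session_order", "duration_min")
  if (!all(need %in% names(s))) {
    stop("sessions table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(s$session_id)) stop("duplicate session_id in sessions table")
  if (any(s$session_order < 1)) stop("session_order must be a positive integer")
  mach_split <- split(cohort$machine, cohort$machine$session_id)
  vit_split <- split(cohort$vitals, cohort$vitals$session_id)
  for (i in seq_len(nrow(s))) {
    sid <- as.character(s$session_id[i])
    m <- mach_split[[sid]]
    v <- vit_split[[sid]]
    if (is.null(m)) stop("session ", sid, ": no machine channel")
    if (is.null(v)) stop("session ", sid, ": no vitals")
    grid <- m$t_min
    if (grid[1] != 0 || any(diff(grid) != 1)) {
      stop("session ", sid, ": minute grid must start at 0 with step 1")
    }
    if (max(grid) != s$duration_min[i]) {
      stop("session ", sid, ": grid end ", max(grid),
           " != duration_min ", s$duration_min[i])
    }
    bad <- which(m$hematocrit_pct <= 0 | m$hematocrit_pct >= 100)
    if (length(bad)) {
      stop("session ", sid, ": hematocrit out of (0, 100) at index ", bad[1])
    }
    if ("rbv_pct" %in% names(m) && abs(m$rbv_pct[1] - 100) > 1e-8) {
      stop("session ", sid, ": rbv_pct at t = 0 must equal 100")
    }
    if (!all(v$t_min %in% grid)) {
      stop("session ", sid, ": vitals times must lie on the minute grid")
    }
    if (!any(v$t_min <= 5)) {
      stop("session ", sid, ": no baseline vitals entry at or before t = 5")
    }
  }
  invisible(cohort)
}

#' @export
print.rbv_cohort <- function(x, ...) {
  cat("rbv_cohort:", nrow(x$sessions), "sessions from",
      length(unique(x$sessions$patient_id)), "patients\n")
  cat("  machine channel:", nrow(x$machine), "minute readings; vitals:",
      nrow(x$vitals), "entries\n")
  if (!is.null(x$truth)) cat("  simulated (ground truth attached)\n")
  invisible(x)
}

#' Read a cohort from CSV files
#'
#' Expects `sessions.csv`, `machine.csv` and `vitals.csv` in `dir` (UTF-8,
#' header row, empty fields as missing). RBV is recomputed from hematocrit if
#' not already present.
#'
#' @param dir directory containing the three CSV files.
#' @param validate check invariants after reading? Default `TRUE`.
#' @return An `rbv_cohort`.
#' @export
read_cohort <- function(dir, validate = TRUE) {
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  sessions <- rd("sessions.csv")
  machine <- rd("machine.csv")
  vitals <- rd("vitals.csv")
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) read.csv(truth_path) else NULL
  if (!"rbv_pct" %in% names(machine)) {
    machine$rbv_pct <- ave(machine$hematocrit_pct, machine$session_id,
                           FUN = function(h) compute_rbv(h))
  }
  rbv_cohort(sessions, machine, vitals, truth = truth, validate = validate)
}

#' Write a cohort to CSV files
#'
#' Writes `sessions.csv`, `machine.csv`, `vitals.csv` (and `truth.csv` when
#' ground truth is attached) into `dir`.
#'
#' @param cohort an `rbv_cohort`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) write.csv(d, file.path(dir, f), row.names = FALSE)
  wr(cohort$sessions, "sessions.csv")
  wr(cohort$machine, "machine.csv")
  wr(cohort$vitals, "vitals.csv")
  if (!is.null(cohort$truth)) wr(cohort$truth, "truth.csv")
  invisible(dir)
}
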