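#' Dynamic time warping distance
#'
#' Accumulated cost of the optimal warping path between two numeric series,
#' with absolute-difference local cost and the unit step pattern
#' (diagonal, horizontal, vertical moves), matching the classic DTW
#' recursion. No global constraint is applied by default; a Sakoe--Chiba
#' band can be requested for long series.
#'
#' DTW compares trajectories by shape while tolerating local time shifts —
#' appropriate for dialysis sessions whose RBV declines follow similar
#' courses at slightly different paces and lengths.
#'
#' @param a,b numeric series (need not be the same length).
#' @param band Sakoe--Chiba half-width in samples, or `NULL` (default) for
#'   unconstrained warping.
#' @return nonnegative accumulated cost; 0 iff the series are equal along a
#'   zero-cost warp.
#' @examples
#' dtw_distance(c(0, 1, 2), c(0, 2))  # 1
#' @export
dtw_distance <- function(a, b, band = NULL) {
  if (length(a) == 0 || length(b) == 0) stop("dtw: series must be non-empty")
  .dtw_cost(as.numeric(a), as.numeric(b),
            if (is.null(band)) -1L else as.integer(band))
}

#' Pairwise DTW distance matrix
#'
#' @param series list of numeric series.
#' @param band optional Sakoe--Chiba half-width.
#' @return symmetric matrix of DTW costs.
#' @export
dtw_distance_matrix <- function(series, band = NULL) {
  .dtw_cost_matrix(lapply(series, as.numeric),
                   if (is.null(band)) -1L else as.integer(band))
}

# Exact k-medoids by exhaustive search over medoid subsets; used when the
# number of candidate subsets is small, and as the oracle the PAM heuristic
# is tested against.
.kmedoids_exact <- function(d, k) {
  n <- nrow(d)
  combs <- utils::combn(n, k)
  best_cost <- Inf
  best <- NULL
  for (ci in seq_len(ncol(combs))) {
    med <- combs[, ci]
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    if (cost < best_cost) {
      best_cost <- cost
      best <- med
    }
  }
  assign <- apply(d[, best, drop = FALSE], 1, which.min)
  list(medoids = best, clustering = assign, cost = best_cost)
}

#' Cluster session RBV trajectories
#'
#' k-medoids clustering on the pairwise DTW distance matrix of per-minute
#' RBV trajectories. Trajectories enter raw (no z-normalization: the RBV
#' level itself carries the risk signal) and unequal session lengths are
#' handled natively by DTW. For small problems (at most `exact_limit`
#' candidate medoid subsets) the optimal medoid set is found by exhaustive
#' search; otherwise the PAM build+swap heuristic (via `cluster::pam`) is
#' used. Both are deterministic, so results do not depend on the seed; the
#' `seed` argument is accepted for interface stability. Average-linkage
#' hierarchical clustering on the same distances is available as an
#' alternative.
#'
#' @param cohort an `rbv_cohort`, or a named list of numeric RBV series.
#' @param k number of clusters (default 3).
#' @param band optional Sakoe--Chiba half-width for the DTW computation.
#' @param method `"kmedoids"` (default) or `"hierarchical"` (average
#'   linkage, cut at `k`).
#' @param exact_limit use exhaustive medoid search when `choose(n, k)` is at
#'   most this (default 2000).
#' @param seed unused (the algorithm is deterministic); kept for interface
#'   stability.
#' @return A list of class `cluster_result`: `labels` (named integer vector
#'   in `1..k` per session), `medoid_ids` (`NULL` for hierarchical),
#'   `cost` (within-cluster total DTW cost to medoids), `k`, and the
#'   `distance` matrix.
#' @export
cluster_trajectories <- function(cohort, k = 3, band = NULL,
                                 method = c("kmedoids", "hierarchical"),
                                 exact_limit = 2000, seed = NULL) {
  method <- match.arg(method)
  series <- if (inherits(cohort, "rbv_cohort")) {
    split(cohort$machine$rbv_pct, cohort$machine$session_id)
  } else {
    cohort
  }
  n <- length(series)
  if (k > n) stop("k = ", k, " exceeds the number of sessions (", n, ")")
  if (any(vapply(series, length, 1L) < 30)) {
    stop("every RBV series must cover at least 30 minutes")
  }
  d <- dtw_distance_matrix(series, band = band)
  ids <- names(series)
  dimnames(d) <- list(ids, ids)
  if (method == "hierarchical") {
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    labels <- stats::cutree(hc, k = k)
    medoids <- NULL
    cost <- NA_real_
  } else if (choose(n, k) <= exact_limit) {
    fit <- .kmedoids_exact(d, k)
    labels <- fit$clustering
    medoids <- fit$medoids
    cost <- fit$cost
  } else {
    fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE)
    labels <- fit$clustering
    medoids <- match(fit$medoids, ids)
    cost <- sum(d[cbind(seq_len(n), medoids[labels])])
  }
  names(labels) <- ids
  structure(list(labels = labels,
                 medoid_ids = if (!is.null(medoids)) ids[medoids],
                 cost = cost, k = k, distance = d),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("DTW k-medoids clustering: k =", x$k, "over", length(x$labels),
      "sessions\n")
  print(table(cluster = x$labels))
  if (!is.na(x$cost)) cat("within-cluster total cost:", format(x$cost), "\n")
  invisible(x)
}

#' Map trajectory clusters to risk groups
#'
#' The cluster with the lowest session-level IDH incidence becomes the
#' low-risk reference; every other cluster is high risk. This generalizes
#' the merge of the two event-rich clusters into one high-risk group against
#' the event-poor reference cluster. Ties on incidence are broken in favour
#' of the larger cluster being low risk.
#'
#' @param labels per-session cluster labels (named by session id).
#' @param session_idh logical vector of session-level IDH (named by session
#'   id, or aligned with `labels`).
#' @return A list of class `risk_groups`: `risk_group` (named character
#'   `"high"`/`"low"` per session), `cluster_risk` (per-cluster map),
#'   `incidence` (per-cluster session-level IDH incidence), `n` (per-cluster
#'   session count).
#' @export
assign_risk_groups <- function(labels, session_idh) {
  if (!is.null(names(session_idh))) {
    session_idh <- session_idh[names(labels)]
  }
  if (anyNA(session_idh)) stop("every clustered session needs an IDH flag")
  inc <- tapply(as.logical(session_idh), labels, mean)
  n <- tapply(labels, labels, length)
  # lowest incidence wins; ties go to the larger cluster
  ord <- order(inc, -n)
  low_cluster <- names(inc)[ord[1]]
  cluster_risk <- setNames(ifelse(names(inc) == low_cluster, "low", "high"),
                           names(inc))
  risk_group <- setNames(unname(cluster_risk[as.character(labels)]),
                         names(labels))
  structure(list(risk_group = risk_group, cluster_risk = cluster_risk,
                 incidence = inc, n = n),
            class = "risk_groups")
}

#' @export
print.risk_groups <- function(x, ...) {
  cat("Risk groups by cluster:\n")
  print(data.frame(cluster = names(x$incidence),
                   n = as.integer(x$n),
                   idh_incidence = round(as.numeric(x$incidence), 3),
                   risk = unname(x$cluster_risk)))
  invisible(x)
}
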