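#' Distance travelled from the injection site
#'
#' Straight-line (Euclidean) distance of every agent from the injection site,
#' in micrometres, summarised per recorded snapshot as a boxplot-style table
#' (quartiles and range). This is displacement, distinct from the cumulative
#' path length used by [shortest_path_agent()].
#'
#' @param record a `sim_record` from [run_simulation()].
#' @param injection_center override for the injection site (pixels).
#' @param per_agent if `TRUE`, return the full `n_snapshots x n_agents`
#'   distance matrix instead of the summary.
#' @return A data frame with `step`, `time_days`, `median`, `q1`, `q3`,
#'   `min`, `max` (um), or a matrix when `per_agent = TRUE`.
#' @export
distance_from_injection <- function(record,
                                    injection_center = record$injection_center,
                                    per_agent = FALSE) {
  stopifnot(inherits(record, "sim_record"))
  ns <- length(record$snapshot_steps)
  n <- record$n_agents
  d <- record$dim
  ctr <- matrix(as.numeric(injection_center), n, d, byrow = TRUE)
  dist <- matrix(0, ns, n)
  for (i in seq_len(ns)) {
    dist[i, ] <- row_norms(matrix(record$snapshots[i, , ], n, d) - ctr) *
      record$pixel_size
  }
  if (per_agent) return(dist)
  qs <- t(apply(dist, 1L, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1),
                names = FALSE))
  data.frame(
    step = record$snapshot_steps,
    time_days = record$snapshot_steps * record$config$dt,
    median = qs[, 3], q1 = qs[, 2], q3 = qs[, 4], min = qs[, 1], max = qs[, 5]
  )
}

#' Percentage of agents on white matter
#'
#' For each recorded snapshot, the percentage of all agents (active and
#' arrived) whose nearest voxel lies on the white-matter mask. If a
#' `tissue_field` is supplied the flags are recomputed by lookup; otherwise
#' the flags stored in the record are used.
#'
#' @param record a `sim_record`.
#' @param tissue optional `tissue_field` for recomputation.
#' @return A data frame with `step`, `time_days` and `wm_pct`.
#' @export
percent_on_white_matter <- function(record, tissue = NULL) {
  stopifnot(inherits(record, "sim_record"))
  ns <- length(record$snapshot_steps)
  n <- record$n_agents
  if (is.null(tissue)) {
    pct <- 100 * rowMeans(record$snapshot_wm)
  } else {
    pct <- numeric(ns)
    wm <- as.vector(tissue$wm_mask)
    for (i in seq_len(ns)) {
      p <- matrix(record$snapshots[i, , ], n, record$dim)
      pct[i] <- 100 * mean(wm[flat_index(nearest_voxel(p), tissue$shape)])
    }
  }
  data.frame(
    step = record$snapshot_steps,
    time_days = record$snapshot_steps * record$config$dt,
    wm_pct = pct
  )
}

#' Cumulative arrival percentage per tumor site
#'
#' Percentage of agents that have ever entered each site's arrival region,
#' counted at first entry (so the series is non-decreasing even when agents
#' are not absorbed), evaluated at the recorded snapshot steps.
#'
#' @param record a `sim_record`.
#' @param cf optional [chemo_field()]; only used for the site count when the
#'   record was produced without one.
#' @return A data frame with `step`, `time_days`, `site` and `arrival_pct`.
#' @export
arrival_percentage <- function(record, cf = NULL) {
  stopifnot(inherits(record, "sim_record"))
  nsites <- if (!is.null(cf)) length(cf$sites) else record$n_sites
  steps <- record$snapshot_steps
  out <- expand.grid(step = steps, site = seq_len(max(nsites, 0L)))
  if (!nsites) {
    return(data.frame(step = integer(), time_days = numeric(),
                      site = integer(), arrival_pct = numeric()))
  }
  pct <- numeric(nrow(out))
  for (r in seq_len(nrow(out))) {
    pct[r] <- 100 * sum(record$arrival_site == out$site[r] &
                          record$arrival_step <= out$step[r], na.rm = TRUE) /
      record$n_agents
  }
  data.frame(
    step = out$step,
    time_days = out$step * record$config$dt,
    site = out$site,
    arrival_pct = pct
  )
}

#' Agent with the shortest path to a tumor site
#'
#' Among agents that arrived at `site`, selects the one with the smallest
#' cumulative path length at first arrival; ties break toward the lower agent
#' id. Returns its recorded trajectory up to arrival.
#'
#' @param record a `sim_record`.
#' @param site site index (default 1).
#' @return A list with `agent`, `path_um`, `arrival_step` and `trajectory`
#'   (snapshot positions up to arrival), or `NULL` with a warning when no
#'   agent arrived.
#' @export
shortest_path_agent <- function(record, site = 1L) {
  stopifnot(inherits(record, "sim_record"))
  ids <- which(record$arrival_site == site)
  if (!length(ids)) {
    warning("no agent arrived at site ", site)
    return(NULL)
  }
  best <- ids[order(record$arrival_path_um[ids], ids)][1L]
  upto <- record$snapshot_steps <= record$arrival_step[best]
  list(
    agent = best,
    path_um = record$arrival_path_um[best],
    arrival_step = record$arrival_step[best],
    trajectory = matrix(record$snapshots[upto, best, ],
                        ncol = record$dim)
  )
}

#' Arrival percentage from cluster counts
#'
#' Converts an experimentally counted number of NSC clusters at a tumor site
#' into an arrival percentage of the administered dose, assuming a fixed
#' number of cells per cluster: `100 * clusters * cells_per_cluster / dose`.
#' An uncertainty on the cluster count is propagated linearly.
#'
#' @param clusters cluster count (mean).
#' @param cells_per_cluster assumed cells per cluster; default 20.
#' @param dose number of administered cells.
#' @param clusters_sd optional uncertainty on `clusters`.
#' @return Named numeric: `percent` (rounded to 2 decimals) and, when
#'   `clusters_sd` is given, `uncertainty`.
#' @examples
#' arrival_percentage_from_clusters(1321, 20, 4e5, clusters_sd = 775.7)
#' @export
arrival_percentage_from_clusters <- function(clusters, cells_per_cluster = 20,
                                             dose, clusters_sd = NULL) {
  if (dose <= 0) stop("dose must be positive")
  if (clusters < 0 || cells_per_cluster <= 0) {
    stop("clusters must be >= 0 and cells_per_cluster > 0")
  }
  out <- c(percent = round(100 * clusters * cells_per_cluster / dose, 2))
  if (!is.null(clusters_sd)) {
    out["uncertainty"] <- round(100 * clusters_sd * cells_per_cluster / dose, 2)
  }
  out
}

#' Arrival percentage from a cell count
#'
#' `100 * cells / dose`, with linear propagation of an optional uncertainty
#' on the cell count.
#'
#' @param cells estimated number of cells at the site.
#' @param dose number of administered cells.
#' @param cells_sd optional uncertainty on `cells`.
#' @return Named numeric: `percent` (rounded to 2 decimals) and, when
#'   `cells_sd` is given, `uncertainty`.
#' @examples
#' arrival_percentage_from_cells(3300, 6e5, cells_sd = 934)
#' @export
arrival_percentage_from_cells <- function(cells, dose, cells_sd = NULL) {
  if (dose <= 0) stop("dose must be positive")
  if (cells < 0) stop("cells must be >= 0")
  out <- c(percent = round(100 * cells / dose, 2))
  if (!is.null(cells_sd)) {
    out["uncertainty"] <- round(100 * cells_sd / dose, 2)
  }
  out
}

#' Tidy metric table for a record
#'
#' Long-format table (one row per snapshot step x statistic x site) combining
#' the distance summary, white-matter occupancy and arrival percentages.
#' A pure function of the record: re-running it on the same record gives an
#' identical table.
#'
#' @param record a `sim_record`.
#' @return A data frame with columns `step`, `time_days`, `metric`, `site`,
#'   `value`.
#' @export
metric_table <- function(record) {
  dist <- distance_from_injection(record)
  wm <- percent_on_white_matter(record)
  rows <- list(
    data.frame(step = dist$step, time_days = dist$time_days,
               metric = "dist_median_um", site = NA_integer_, value = dist$median),
    data.frame(step = dist$step, time_days = dist$time_days,
               metric = "dist_q1_um", site = NA_integer_, value = dist$q1),
    data.frame(step = dist$step, time_days = dist$time_days,
               metric = "dist_q3_um", site = NA_integer_, value = dist$q3),
    data.frame(step = wm$step, time_days = wm$time_days,
               metric = "wm_pct", site = NA_integer_, value = wm$wm_pct)
  )
  if (record$n_sites > 0) {
    arr <- arrival_percentage(record)
    rows <- c(rows, list(
      data.frame(step = arr$step, time_days = arr$time_days,
                 metric = "arrival_pct", site = arr$site, value = arr$arrival_pct)
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
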