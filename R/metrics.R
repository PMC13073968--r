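#' Nearest-rank percentile
#'
#' The value at position `ceiling(p * n)` of the ascending sorted sample.
#' Chosen over interpolating definitions because it is unambiguous and
#' reproducible on small samples.
#'
#' @param x Numeric vector (non-empty).
#' @param p Probability in (0, 1].
#' @return A single value of `x`.
#' @export
nearest_rank <- function(x, p) {
  stopifnot(length(x) > 0L, p > 0, p <= 1)
  sort(x)[ceiling(p * length(x))]
}

#' Network travel-time statistics
#'
#' Mean, nearest-rank 90th percentile, and maximum of realized travel
#' minutes over allocated units, unweighted per municipality. Full
#' precision is retained; rounding happens only at report time. With zero
#' allocated units an empty-stats marker (all NA, n = 0) is returned
#' rather than an error.
#'
#' @param result An `hs_allocation`.
#' @param weighted If `TRUE`, mean is population-weighted instead of the
#'   default unweighted per-municipality mean (p90 and max are order
#'   statistics and stay unweighted).
#' @param territory Required when `weighted = TRUE`, to look up
#'   populations.
#' @return A one-row tibble: `n_allocated`, `mean_minutes`, `p90_minutes`,
#'   `max_minutes`.
#' @export
travel_time_stats <- function(result, weighted = FALSE, territory = NULL) {
  rec <- result$records
  m <- rec$minutes[rec$status == "allocated"]
  if (length(m) == 0L) {
    return(tibble::tibble(n_allocated = 0L, mean_minutes = NA_real_,
                          p90_minutes = NA_real_, max_minutes = NA_real_))
  }
  mean_m <- if (weighted) {
    stopifnot(!is.null(territory))
    w <- unit_populations(territory)[rec$code[rec$status == "allocated"]]
    sum(m * w) / sum(w)
  } else {
    mean(m)
  }
  tibble::tibble(
    n_allocated = length(m),
    mean_minutes = mean_m,
    p90_minutes = nearest_rank(m, 0.9),
    max_minutes = max(m)
  )
}

#' Share of population allocated
#'
#' `100 * allocated population / total population` over all demand units.
#'
#' @param result An `hs_allocation`.
#' @param territory The `hs_territory` the result was computed on.
#' @return Percentage in `[0, 100]`.
#' @export
population_allocated_fraction <- function(result, territory) {
  total <- sum(territory$units$population)
  if (total == 0) {
    stop("hubspoke: total population is zero; allocated fraction undefined",
         call. = FALSE)
  }
  rec <- result$records
  pops <- unit_populations(territory)
  100 * sum(pops[rec$code[rec$status == "allocated"]]) / total
}

#' Per-node catchment summary
#'
#' For each node: population served, unweighted mean realized minutes and
#' km over assigned units, and catchment population density (population
#' served divided by the summed land area of assigned units, inhabitants
#' per km2). Nodes with no assigned units are reported with `served = 0`
#' and NA statistics.
#'
#' @param result An `hs_allocation`.
#' @param territory The matching `hs_territory`.
#' @return A tibble, one row per node, in node-code order.
#' @export
per_node_summary <- function(result, territory) {
  rec <- result$records
  alloc <- rec[rec$status == "allocated", , drop = FALSE]
  pops <- unit_populations(territory)
  areas <- stats::setNames(territory$units$area, territory$units$code)

  one <- function(nd) {
    rows <- alloc[alloc$node == nd, , drop = FALSE]
    if (nrow(rows) == 0L) {
      return(tibble::tibble(served = 0L, mean_minutes = NA_real_,
                            mean_km = NA_real_, area = NA_real_,
                            density = NA_real_))
    }
    served <- sum(pops[rows$code])
    area <- sum(areas[rows$code])
    tibble::tibble(
      served = as.integer(served),
      mean_minutes = mean(rows$minutes),
      mean_km = mean(rows$km),
      area = area,
      density = served / area
    )
  }
  stats <- dplyr::bind_rows(lapply(territory$nodes$code, one))
  dplyr::bind_cols(
    tibble::tibble(node = territory$nodes$code, role = territory$nodes$role),
    stats
  )
}

#' Capacity-violation report
#'
#' One entry per node whose served population exceeds its cap, sorted by
#' excess descending; an empty report means the allocation is
#' cap-compliant. A node serving exactly its cap is compliant.
#'
#' @param result An `hs_allocation`, or a loads tibble with columns
#'   `node`, `served`, `cap` (so printed per-node loads can be audited
#'   directly without re-running an allocation).
#' @return A tibble with columns `node`, `served`, `cap`, `excess`.
#' @export
violation_report <- function(result) {
  loads <- if (inherits(result, "hs_allocation")) result$loads else result
  stopifnot(all(c("node", "served", "cap") %in% names(loads)))
  loads <- tibble::as_tibble(loads)
  loads$excess <- pmax(0L, as.integer(loads$served) - as.integer(loads$cap))
  violations_from_loads(loads)[, c("node", "served", "cap", "excess")]
}

#' Multi-threshold scenario table
#'
#' Runs [allocate_scenario()] at each cut-off and tabulates, for the
#' baseline and cap-compliant outputs: units allocated and excluded,
#' percent of population allocated, mean / 90th-percentile / maximum
#' realized travel minutes, number of cap violations and a short
#' violation summary.
#'
#' @param territory An `hs_territory`.
#' @param cutoffs Numeric vector of cut-offs in minutes (non-empty;
#'   duplicates removed with a warning).
#' @param config Base `hs_config`; its cutoff is replaced per scenario.
#' @param digits Rounding applied to the displayed time columns (default
#'   0, matching whole-minute reporting); set `NA` to disable.
#' @return A tibble with one row per cut-off and mode.
#' @export
run_scenarios <- function(territory, cutoffs,
                          config = scenario_config(cutoff = 30),
                          digits = NA) {
  if (length(cutoffs) == 0L) {
    stop("hubspoke: at least one cut-off is required", call. = FALSE)
  }
  if (anyDuplicated(cutoffs)) {
    warning("hubspoke: duplicate cut-offs removed", call. = FALSE)
    cutoffs <- unique(cutoffs)
  }
  rows <- lapply(cutoffs, function(co) {
    cfg <- config
    cfg$cutoff <- as.numeric(co)
    pair <- allocate_scenario(territory, cfg)
    dplyr::bind_rows(lapply(c("baseline", "cap_compliant"), function(mode) {
      res <- pair[[mode]]
      st <- travel_time_stats(res)
      viol <- violation_report(res)
      tibble::tibble(
        cutoff = as.numeric(co),
        mode = mode,
        units_allocated = sum(res$records$status == "allocated"),
        units_excluded = sum(res$records$status == "excluded"),
        population_pct = population_allocated_fraction(res, territory),
        mean_minutes = st$mean_minutes,
        p90_minutes = st$p90_minutes,
        max_minutes = st$max_minutes,
        n_violations = nrow(viol),
        violations = if (nrow(viol) == 0L) "none" else {
          paste0(viol$node, " +", viol$excess, collapse = "; ")
        },
        n_moves = nrow(res$moves)
      )
    }))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.na(digits)) {
    for (col in c("mean_minutes", "p90_minutes", "max_minutes")) {
      out[[col]] <- round(out[[col]], digits)
    }
  }
  out
}
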