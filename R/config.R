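#' Scenario configuration
#'
#' Bundles the planning parameters of one allocation scenario.
#'
#' @param cutoff Travel-time cut-off in minutes (> 0). Units whose nearest
#'   node lies beyond the cut-off are infeasible under the scenario.
#' @param margin Near-optimal candidate margin in `[0, 1)`: nodes within
#'   `(1 + margin)` times a unit's minimum feasible travel time form its
#'   candidate set. Default 0.05 (5 percent).
#' @param hub_cap,spoke_cap Default population caps by node role, in
#'   residents (50,000 / 40,000 unless overridden per node in the roster).
#' @param mode `"baseline"` (proximity-first, overloads recorded but not
#'   prevented) or `"cap_compliant"` (overloads resolved by iterative
#'   reallocation).
#' @param strict_exclusion If `TRUE` (default) units with no node within
#'   the cut-off are excluded and reported; if `FALSE` they are
#'   force-assigned to their globally nearest node and flagged.
#' @param pin_hosts If `TRUE` (default) a unit hosting a node is assigned
#'   to its own node and never moved during reallocation.
#' @param priority_count Whether priority criterion (i) counts members of
#'   the near-optimal candidate set (`"candidates"`, default) or of the
#'   full feasible set (`"feasible"`).
#' @return An object of class `hs_config`.
#' @export
scenario_config <- function(cutoff,
                            margin = 0.05,
                            hub_cap = 50000L,
                            spoke_cap = 40000L,
                            mode = c("baseline", "cap_compliant"),
                            strict_exclusion = TRUE,
                            pin_hosts = TRUE,
                            priority_count = c("candidates", "feasible")) {
  mode <- match.arg(mode)
  priority_count <- match.arg(priority_count)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0,
            is.numeric(margin), length(margin) == 1L,
            margin >= 0, margin < 1,
            hub_cap > 0, spoke_cap > 0)
  structure(
    list(cutoff = as.numeric(cutoff),
         margin = as.numeric(margin),
         hub_cap = as.integer(hub_cap),
         spoke_cap = as.integer(spoke_cap),
         mode = mode,
         strict_exclusion = isTRUE(strict_exclusion),
         pin_hosts = isTRUE(pin_hosts),
         priority_count = priority_count),
    class = "hs_config"
  )
}

#' @export
print.hs_config <- function(x, ...) {
  cat("<hs_config> cutoff ", x$cutoff, " min, margin ", x$margin,
      ", caps ", x$hub_cap, "/", x$spoke_cap, " (hub/spoke), mode ",
      x$mode, "\n", sep = "")
  invisible(x)
}

# Effective cap per node: roster override when present, else role default.
effective_caps <- function(territory, config) {
  nodes <- territory$nodes
  caps <- ifelse(nodes$role == "hub", config$hub_cap, config$spoke_cap)
  caps <- ifelse(is.na(nodes$cap), caps, nodes$cap)
  stats::setNames(as.numeric(caps), nodes$code)
}
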